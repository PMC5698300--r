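# Expression atlas: tissue assignment at the linear-256 (log2 = 8)
# threshold, relative-expression centering, co-expression clustering at a
# Pearson-distance cut, and descriptive condition contrasts.

#' Build an expression matrix container
#'
#' Wraps a genes x samples matrix of log2 (RMA-scale) intensities and its
#' sample metadata into a `SummarizedExperiment` (assay "log2"; colData
#' columns `tissue`, `condition`, `platform`).
#'
#' @param values numeric matrix, genes in rows, samples in columns; finite
#'   values, unique row and column names.
#' @param sample_meta data.frame with one row per sample (rownames =
#'   sample ids) and at least a `tissue` column.
#' @return a `SummarizedExperiment`.
#' @export
expressionMatrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("gene and sample labels must be unique")
  }
  if (!all(colnames(values) %in% rownames(sample_meta))) {
    stop("every sample needs a metadata record")
  }
  if (!"tissue" %in% names(sample_meta)) stop("sample_meta needs a tissue column")
  meta <- sample_meta[colnames(values), , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    colData = S4Vectors::DataFrame(meta))
}

.exprValues <- function(m) {
  if (methods::is(m, "SummarizedExperiment")) {
    SummarizedExperiment::assay(m, "log2")
  } else m
}

.exprTissues <- function(m, sample_meta = NULL) {
  if (methods::is(m, "SummarizedExperiment")) {
    as.character(SummarizedExperiment::colData(m)$tissue)
  } else {
    if (is.null(sample_meta)) stop("sample metadata required")
    as.character(sample_meta[colnames(m), "tissue"])
  }
}

#' Assign tissue (Plant Ontology style) labels to genes
#'
#' A gene is assigned a tissue label when its mean log2 intensity over that
#' tissue's replicate samples reaches log2 of the linear threshold
#' (default 256, i.e. log2 value 8). The comparison is inclusive.
#'
#' @param m a `SummarizedExperiment` from [expressionMatrix()] (or a
#'   matrix plus `sample_meta`).
#' @param threshold_abs threshold on the linear intensity scale (default
#'   256; converted internally to log2).
#' @param stat per-tissue summary statistic, "mean" (default, replicates
#'   averaged) or "max".
#' @param sample_meta metadata when `m` is a plain matrix.
#' @return data.frame with columns `gene`, `tissue`, one row per call;
#'   genes below threshold everywhere are absent.
#' @export
assignTissueOntology <- function(m, threshold_abs = 256, stat = c("mean", "max"),
                                 sample_meta = NULL) {
  stat <- match.arg(stat)
  vals <- .exprValues(m)
  tissues <- .exprTissues(m, sample_meta)
  thr <- log2(threshold_abs)
  rows <- list()
  for (tis in unique(tissues)) {
    cols <- which(tissues == tis)
    if (length(cols) == 0L) {
      warning("tissue with zero samples skipped: ", tis)
      next
    }
    v <- if (stat == "mean") rowMeans(vals[, cols, drop = FALSE]) else
      apply(vals[, cols, drop = FALSE], 1L, max)
    hit <- which(v >= thr)
    if (length(hit)) {
      rows[[tis]] <- data.frame(gene = rownames(vals)[hit], tissue = tis,
                                stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), tissue = character(0))
  rownames(out) <- NULL
  out[order(out$gene, out$tissue), , drop = FALSE]
}

#' Center expression on the average per gene
#'
#' Subtracts each gene's row mean: relative expression centered on the
#' average. Idempotent.
#'
#' @param m `SummarizedExperiment` or matrix.
#' @return same container type with centered values.
#' @export
centerRelative <- function(m) {
  vals <- .exprValues(m)
  centered <- vals - rowMeans(vals)
  if (methods::is(m, "SummarizedExperiment")) {
    SummarizedExperiment::assay(m, "log2") <- centered
    m
  } else centered
}

.pearsonDistances <- function(vals) {
  keep <- apply(vals, 1L, function(x) stats::sd(x) > 0)
  if (any(!keep)) {
    warning("zero-variance gene(s) excluded from clustering: ",
            paste(rownames(vals)[!keep], collapse = ", "))
  }
  vals <- vals[keep, , drop = FALSE]
  d <- 1 - stats::cor(t(vals))
  list(d = stats::as.dist(d), genes = rownames(vals))
}

#' Co-expression clusters at a Pearson-distance cut
#'
#' Distance is 1 - PCC between gene profiles; clusters are obtained by
#' average-linkage hierarchical agglomeration, cutting the tree so that
#' merged groups have linkage distance strictly below the threshold
#' (distance < 0.2 means PCC > 0.8 between profiles, on average between
#' groups). Singletons are dropped; clusters at a smaller threshold are
#' refinements of those at a larger one.
#'
#' @param m `SummarizedExperiment` or matrix; >= 2 genes and >= 3 samples.
#' @param distance_threshold 1 - PCC cut (default 0.2).
#' @param sample_meta unused for clustering; accepted for symmetry.
#' @return list of clusters, each a list with `members` (gene names,
#'   sorted) and `max_internal_distance`.
#' @export
coexpressionClusters <- function(m, distance_threshold = 0.2,
                                 sample_meta = NULL) {
  vals <- .exprValues(m)
  if (nrow(vals) < 2L) stop("need at least 2 genes")
  if (ncol(vals) < 3L) stop("need at least 3 samples for a Pearson distance")
  pd <- .pearsonDistances(vals)
  hc <- stats::hclust(pd$d, method = "average")
  grp <- stats::cutree(hc, h = distance_threshold - 1e-9)
  dm <- as.matrix(pd$d)
  out <- list()
  for (g in sort(unique(grp))) {
    members <- sort(pd$genes[grp == g])
    if (length(members) < 2L) next
    out[[length(out) + 1L]] <- list(
      members = members,
      max_internal_distance = max(dm[members, members]))
  }
  # deterministic ordering by first member label
  if (length(out)) {
    out <- out[order(vapply(out, function(cl) cl$members[1], character(1)))]
  }
  out
}

#' Co-expression neighbors of one gene
#'
#' All genes at Pearson distance strictly below the threshold from the
#' query, ranked by ascending distance.
#'
#' @param m `SummarizedExperiment` or matrix.
#' @param gene query gene name.
#' @param distance_threshold 1 - PCC cut (default 0.2).
#' @return data.frame `partner`, `distance`, `pcc`, ascending by distance;
#'   zero rows when no gene is within the threshold.
#' @export
neighborsOf <- function(m, gene, distance_threshold = 0.2) {
  vals <- .exprValues(m)
  if (!gene %in% rownames(vals)) stop("unknown gene: ", gene)
  q <- vals[gene, ]
  if (stats::sd(q) == 0) stop("query gene has zero variance")
  others <- setdiff(rownames(vals), gene)
  pcc <- vapply(others, function(g) {
    x <- vals[g, ]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(q, x)
  }, numeric(1))
  d <- 1 - pcc
  keep <- !is.na(d) & d < distance_threshold
  out <- data.frame(partner = others[keep], distance = d[keep],
                    pcc = pcc[keep], stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Descriptive log2 condition contrast
#'
#' Per-gene mean difference between two sample groups on the log2 scale;
#' purely descriptive (no inferential statistics). Swapping the groups
#' negates the table.
#'
#' @param m `SummarizedExperiment` or matrix.
#' @param group_a,group_b character vectors of sample names.
#' @return data.frame `gene`, `log2_diff` (mean(group_a) - mean(group_b)).
#' @export
conditionContrast <- function(m, group_a, group_b) {
  vals <- .exprValues(m)
  missing_s <- setdiff(c(group_a, group_b), colnames(vals))
  if (length(missing_s)) {
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  }
  diff <- rowMeans(vals[, group_a, drop = FALSE]) -
    rowMeans(vals[, group_b, drop = FALSE])
  data.frame(gene = rownames(vals), log2_diff = unname(diff),
             stringsAsFactors = FALSE)
}
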