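# Distance-based phylogeny: column-coverage filtering, p/Poisson protein
# distances, an in-package Saitou-Nei neighbor-joining implementation with
# deterministic tie-breaking, bootstrap supports on the full-data tree's
# bipartitions, low-support branch collapsing, and bootstrap-thresholded
# subclass assignment against reference genes.

#' Filter alignment columns by site coverage
#'
#' Retains columns whose fraction of non-gap residues is at least
#' `min_coverage` (default 0.95, i.e. positions with less than 95% site
#' coverage are eliminated). Column order is preserved.
#'
#' @param msa aligned proteins (`AAStringSet`, equal-length character
#'   vector, or character matrix).
#' @param min_coverage minimum non-gap fraction per column.
#' @return filtered alignment, same container type as a character matrix is
#'   returned as a matrix, otherwise an `AAStringSet`.
#' @export
filterColumns <- function(msa, min_coverage = 0.95) {
  m <- asMsaMatrix(msa)
  cov <- colMeans(m != "-" & m != ".")
  keep <- cov >= min_coverage
  if (!any(keep)) stop("all columns removed by the coverage filter")
  out <- m[, keep, drop = FALSE]
  if (is.matrix(msa) && is.character(msa)) out else msaMatrixToSet(out)
}

#' Pairwise protein distances
#'
#' p-distance = mismatches / compared sites with pairwise deletion of gap
#' sites; the Poisson correction is d = -ln(1 - p). (The multiple-hit
#' corrections stand in for matrix-based models; a likelihood JTT analysis
#' is an external alternative whose Newick output the pipeline can ingest.)
#'
#' @param msa aligned proteins, >= 3 taxa.
#' @param model "p" for raw p-distance, "poisson" for the Poisson
#'   correction.
#' @return symmetric numeric matrix with zero diagonal, labelled by taxa.
#' @examples
#' proteinDistance(c(a = "AAAA", b = "AAAC", c = "AACC"), model = "p")
#' @export
proteinDistance <- function(msa, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- asMsaMatrix(msa)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop("no comparable sites between ", labels[i], " and ", labels[j])
      }
      p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      if (model == "poisson") {
        if (p >= 1) stop("Poisson correction undefined at p >= 1 for pair ",
                         labels[i], ", ", labels[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining on a symmetric distance matrix.
#' Ties in the Q-criterion are broken by the lexicographically smallest
#' label pair (each cluster is represented by its smallest member label),
#' so the topology is deterministic across platforms. Consistent: exact
#' topology and branch lengths are recovered on additive matrices.
#'
#' @param d symmetric numeric matrix with labels (as from
#'   [proteinDistance()]).
#' @return an unrooted `ape::phylo` tree.
#' @export
njTree <- function(d) {
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must carry labels")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  # active clusters: newick fragment + representative (smallest) label
  node <- labels
  rep_lab <- labels
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (sorted) representative label pair
    keys <- apply(cand, 1L, function(ij) {
      paste(sort(c(rep_lab[ij[1]], rep_lab[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_node <- sprintf("(%s:%.10g,%s:%.10g)", node[i], li, node[j], lj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    node <- c(node[keep], new_node)
    rep_lab <- c(rep_lab[keep], new_rep)
    D <- D2
  }
  # final three-point resolution
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    node[1], la, node[2], lb, node[3], lc)
  ape::read.tree(text = newick)
}

# Non-trivial bipartitions of an unrooted tree, keyed canonically.
# Returns a named character vector: node number (as name) -> split key.
.splitKeys <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ntip <- length(labs)
  keys <- character(0)
  for (k in seq_along(pp)) {
    node <- ntip + k
    side <- labs[pp[[k]]]
    if (length(side) >= ntip - 1L) next       # trivial: root / near-whole set
    if (length(side) <= 1L) next              # trivial leaf split
    if (ref %in% side) side <- setdiff(labs, side)
    keys[as.character(node)] <- paste(sort(side), collapse = "|")
  }
  keys
}

# Contract internal edges of `tree` whose child-node support is below `thr`.
.collapseTree <- function(tree, node_supports, thr) {
  drop <- which(!is.na(node_supports) & node_supports < thr)
  if (!length(drop)) return(tree)
  t2 <- tree
  nodes <- ape::Ntip(t2) + drop
  edge_idx <- which(t2$edge[, 2] %in% nodes)
  t2$edge.length[edge_idx] <- 0
  t2 <- ape::di2multi(t2, tol = 1e-12)
  t2
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree for each replicate, and reports, for every internal
#' bipartition of the full-data tree, the percentage of replicates
#' containing it. Edges below `collapse_below` percent are contracted to
#' polytomies in the collapsed tree; pre-collapse supports are always kept.
#'
#' @param msa aligned proteins (already coverage-filtered; see
#'   [filterColumns()]).
#' @param n_reps bootstrap replicates (default 100).
#' @param seed integer seed; identical seeds give identical supports.
#' @param collapse_below collapse threshold in percent (default 30; 0
#'   disables collapsing).
#' @param model distance model passed to [proteinDistance()].
#' @return a [SupportTree-class].
#' @export
bootstrapTree <- function(msa, n_reps = 100L, seed = 1L,
                          collapse_below = 30, model = "poisson") {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  m <- asMsaMatrix(msa)
  full <- njTree(proteinDistance(m, model = model))
  keys <- .splitKeys(full)
  counts <- setNames(numeric(length(keys)), keys)
  withSeed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample(ncol(m), ncol(m), replace = TRUE)
      bt <- njTree(proteinDistance(m[, cols, drop = FALSE], model = model))
      bk <- .splitKeys(bt)
      hit <- keys[keys %in% bk]
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- rep(NA_real_, full$Nnode)
  idx <- as.integer(names(keys)) - ape::Ntip(full)
  supports[idx] <- 100 * counts[keys] / n_reps
  full$node.label <- ifelse(is.na(supports), "",
                            format(round(supports, 1), trim = TRUE))
  collapsed <- if (collapse_below > 0) {
    .collapseTree(full, supports, collapse_below)
  } else full
  new("SupportTree", tree = full, supports = supports,
      collapsed = collapsed, collapse_below = as.numeric(collapse_below))
}

#' Assign subclasses from a supported tree
#'
#' A query gene is assigned subclass s when it lies inside a clade of the
#' tree (as rooted/displayed) with bootstrap support at or above `min_support`
#' containing at least one reference gene of subclass s and no reference
#' gene of another subclass. When only lower-support pure clades exist the
#' gene is left unassigned with evidence "phylogeny+motif-needed" (the
#' motif stream must complement the phylogeny); when every containing
#' clade mixes reference subclasses it is unassigned regardless of
#' support.
#'
#' @param st a [SupportTree-class] (or `phylo` with numeric node labels,
#'   coerced via [supportTree()]).
#' @param reference named character vector: reference gene -> subclass
#'   letter.
#' @param min_support assignment threshold in percent (default 70).
#'   Raising it never gains assignments.
#' @return data.frame with one row per query gene: `gene`, `subclass` (NA
#'   when not assigned), `support` (best supporting clade), `status`
#'   ("assigned", "motif_needed", "unassigned"), `evidence`.
#' @examples
#' tr <- ape::read.tree(text = "((q:1,refd:1)85:1,(refa:1,refc:1)99:1,o:1);")
#' assignSubclasses(tr, c(refd = "d", refa = "a", refc = "c"))
#' @export
assignSubclasses <- function(st, reference, min_support = 70) {
  if (inherits(st, "phylo")) st <- supportTree(st)
  tree <- st@tree
  supports <- st@supports
  tips <- tree$tip.label
  missing_ref <- setdiff(names(reference), tips)
  if (length(missing_ref)) {
    stop("reference gene(s) absent from tree: ",
         paste(missing_ref, collapse = ", "))
  }
  queries <- setdiff(tips, names(reference))
  ntip <- length(tips)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sides <- lapply(seq_along(pp), function(k) labs[pp[[k]]])
  node_of <- ntip + seq_along(pp)
  rows <- lapply(queries, function(q) {
    best <- NULL
    for (k in seq_along(sides)) {
      s <- supports[node_of[k] - ntip]
      if (is.na(s)) next
      side <- sides[[k]]
      if (length(side) >= ntip) next  # root clade is trivial
      if (!(q %in% side)) next
      refs_in <- reference[intersect(names(reference), side)]
      if (length(refs_in) == 0L) next
      if (length(unique(refs_in)) != 1L) next
      cand <- list(subclass = unname(refs_in[1]), support = s,
                   size = length(side))
      if (is.null(best) || cand$support > best$support ||
          (cand$support == best$support && cand$size < best$size)) {
        best <- cand
      }
    }
    if (is.null(best)) {
      data.frame(gene = q, subclass = NA_character_, support = NA_real_,
                 status = "unassigned", evidence = "phylogeny+motif-needed",
                 stringsAsFactors = FALSE)
    } else if (best$support >= min_support) {
      data.frame(gene = q, subclass = best$subclass, support = best$support,
                 status = "assigned", evidence = "phylogeny",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = q, subclass = NA_character_, support = best$support,
                 status = "motif_needed", evidence = "phylogeny+motif-needed",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), subclass = character(0),
                      support = numeric(0), status = character(0),
                      evidence = character(0))
  }
  out
}
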