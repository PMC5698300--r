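# Orthology: all-vs-all local alignment, retention filtering, reciprocal
# best hits, and the per-gene x species presence matrix.
#
# Local alignments are Smith-Waterman (Biostrings::pairwiseAlignment,
# BLOSUM62, gap open 11 / extend 1). E-values use the Karlin-Altschul form
# E = K * m * n * exp(-lambda * S) with fixed gapped-BLOSUM62 parameters
# (lambda = 0.267, K = 0.041) and search space m * n; exact parity with any
# BLAST release is not a goal, the filter's behaviour at the retention
# thresholds is the contract.

.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Best local alignment hits for every ordered pair
#'
#' For each (query, subject) pair computes the optimal Smith-Waterman local
#' alignment and reports its score, identity (identical residues over
#' aligned columns, gaps included in the denominator), alignment length and
#' Karlin-Altschul e-value. Deterministic.
#'
#' @param setA query proteins (`AAStringSet` or named character).
#' @param setB subject proteins.
#' @param gap_opening,gap_extension gap penalties (defaults 11 and 1).
#' @param substitution_matrix scoring matrix name (default "BLOSUM62").
#' @return data.frame with columns `query`, `subject`, `score`, `identity`,
#'   `aln_len`, `e_value`; one row per ordered pair.
#' @export
allVsAllHits <- function(setA, setB, gap_opening = 11, gap_extension = 1,
                         substitution_matrix = "BLOSUM62") {
  ok <- function(s) grepl("^[ACDEFGHIKLMNPQRSTVWYXBZ]+$", as.character(s))
  if (!all(ok(setA)) || !all(ok(setB))) {
    stop("sequence with illegal characters")
  }
  if (is.character(setA)) setA <- Biostrings::AAStringSet(setA)
  if (is.character(setB)) setB <- Biostrings::AAStringSet(setB)
  if (length(setA) == 0L || length(setB) == 0L) {
    stop("both protein sets must be nonempty")
  }
  qn <- names(setA); sn <- names(setB)
  if (is.null(qn)) qn <- paste0("q", seq_along(setA))
  if (is.null(sn)) sn <- paste0("s", seq_along(setB))
  rows <- vector("list", length(setB))
  for (j in seq_along(setB)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = setA, subject = setB[[j]], type = "local",
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_opening, gapExtension = gap_extension)
    w <- Biostrings::nchar(aln)
    idn <- Biostrings::nmatch(aln) / pmax(w, 1L)
    s <- Biostrings::score(aln)
    mn <- as.numeric(Biostrings::width(setA)) *
      as.numeric(Biostrings::width(setB)[j])
    e <- .KA_K * mn * exp(-.KA_LAMBDA * s)
    rows[[j]] <- data.frame(query = qn, subject = sn[j], score = s,
                            identity = idn, aln_len = w, e_value = e,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the retention filter to alignment hits
#'
#' Strict inequalities as the rules are stated: a hit is retained when its
#' e-value is lower than `e_max` and its identity is higher than
#' `identity_min`. Tightening either threshold never adds hits.
#'
#' @param hits data.frame from [allVsAllHits()].
#' @param e_max e-value ceiling (default 1e-20, strict `<`).
#' @param identity_min identity floor (default 0.40, strict `>`).
#' @return the retained subset of `hits`.
#' @export
retainHits <- function(hits, e_max = 1e-20, identity_min = 0.40) {
  hits[hits$e_value < e_max & hits$identity > identity_min, , drop = FALSE]
}

# Best retained hit per query; ties resolved by higher identity then
# lexicographically smaller subject id. Tie events are recorded.
.bestHits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), tie = logical(0)))
  }
  rows <- lapply(split(hits, hits$query), function(h) {
    top <- h[h$score == max(h$score), , drop = FALSE]
    tie <- nrow(top) > 1L
    top <- top[order(-top$identity, top$subject), , drop = FALSE]
    data.frame(query = top$query[1], subject = top$subject[1],
               score = top$score[1], tie = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two gene sets
#'
#' Pairs (A, B) such that B is A's best retained hit in the subject set and
#' A is B's best retained hit back. Score ties are broken deterministically
#' (higher identity, then lexicographic id) and flagged.
#'
#' @param hitsAB retained hits A -> B (apply [retainHits()] first, or pass
#'   raw hits and the thresholds via `...`).
#' @param hitsBA retained hits B -> A on the same sets.
#' @param ... optional `e_max` / `identity_min` forwarded to
#'   [retainHits()] when filtering has not been applied.
#' @return data.frame with columns `a`, `b`, `score_ab`, `score_ba`,
#'   `tie` (either direction's best involved a score tie).
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA, ...) {
  dots <- list(...)
  if (length(dots)) {
    hitsAB <- do.call(retainHits, c(list(hitsAB), dots))
    hitsBA <- do.call(retainHits, c(list(hitsBA), dots))
  }
  bestAB <- .bestHits(hitsAB)
  bestBA <- .bestHits(hitsBA)
  if (nrow(bestAB) == 0L || nrow(bestBA) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      score_ab = numeric(0), score_ba = numeric(0),
                      tie = logical(0)))
  }
  back <- setNames(bestBA$subject, bestBA$query)
  keep <- !is.na(back[bestAB$subject]) & back[bestAB$subject] == bestAB$query
  keep[is.na(keep)] <- FALSE
  ab <- bestAB[keep, , drop = FALSE]
  tie_ba <- setNames(bestBA$tie, bestBA$query)
  score_ba <- setNames(bestBA$score, bestBA$query)
  out <- data.frame(a = ab$query, b = ab$subject, score_ab = ab$score,
                    score_ba = unname(score_ba[ab$subject]),
                    tie = ab$tie | unname(tie_ba[ab$subject]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$a), , drop = FALSE]
}

#' Gene x species orthology presence matrix
#'
#' For every query gene and species: "one_to_one" when a reciprocal best
#' hit exists, "homolog_only" when retained hits exist but no RBH,
#' "no_match" otherwise. Mirrors the green/white/black presence matrices
#' used to chart family-wide orthology against sequenced genomes.
#'
#' @param vitis_set query proteins (`AAStringSet`).
#' @param species_sets named list of subject proteomes.
#' @param e_max,identity_min retention thresholds (see [retainHits()]).
#' @return list with `matrix` (character matrix gene x species),
#'   `results` (long data.frame `gene`, `species`, `category`, `partner`),
#'   `n_orthologs` (named integer, species with an RBH per gene) and
#'   `no_ortholog_genes` (genes with zero RBHs across all species).
#' @export
orthologPresenceMatrix <- function(vitis_set, species_sets,
                                   e_max = 1e-20, identity_min = 0.40) {
  if (length(species_sets) == 0L) stop("empty species set")
  if (is.null(names(species_sets))) {
    stop("species_sets must be a named list")
  }
  genes <- names(vitis_set)
  mat <- matrix("no_match", nrow = length(genes),
                ncol = length(species_sets),
                dimnames = list(genes, names(species_sets)))
  rows <- list()
  for (sp in names(species_sets)) {
    sset <- species_sets[[sp]]
    hitsAB <- retainHits(allVsAllHits(vitis_set, sset),
                         e_max = e_max, identity_min = identity_min)
    hitsBA <- retainHits(allVsAllHits(sset, vitis_set),
                         e_max = e_max, identity_min = identity_min)
    rbh <- reciprocalBestHits(hitsAB, hitsBA)
    partner <- setNames(rbh$b, rbh$a)
    has_hit <- genes %in% hitsAB$query
    cat_sp <- ifelse(genes %in% rbh$a, "one_to_one",
                     ifelse(has_hit, "homolog_only", "no_match"))
    mat[, sp] <- cat_sp
    rows[[sp]] <- data.frame(gene = genes, species = sp, category = cat_sp,
                             partner = unname(partner[genes]),
                             stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  n_orth <- rowSums(mat == "one_to_one")
  list(matrix = mat, results = results,
       n_orthologs = n_orth,
       no_ortholog_genes = genes[n_orth == 0L])
}
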