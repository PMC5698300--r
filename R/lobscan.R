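# LOB-domain motif grammar scanning and Class I/II classification.
#
# The scanner is deliberately positional rather than regex-based: each block
# is a fixed-width frame with anchor offsets, so matches are exact, overlap
# is handled naturally, and the semantics ("X never matches an anchor") are
# explicit. Tests compare it against a naive position-by-position oracle.

.charsAt <- function(chars, pos) chars[pos]

.seqChars <- function(seq) {
  if (methods::is(seq, "XString")) seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

# Zipper anchor offsets (0-based) for n anchors spaced X6, X3, X6, X3, ...
.zipperOffsets <- function(n) {
  gaps <- rep(c(6L, 3L), length.out = n - 1L)
  cumsum(c(0L, gaps + 1L))
}

#' Scan for the CX2CX6CX3C zinc-finger-like C-block
#'
#' Finds all (possibly overlapping) occurrences of the 15-residue frame
#' C X2 C X6 C X3 C. Anchor positions must be literal cysteine; the wildcard
#' positions accept any residue (including ambiguity code X, which never
#' matches a C anchor).
#'
#' @param seq a protein sequence (character scalar or `AAString`).
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   leftmost match first; zero rows when there is no match or the sequence
#'   is empty.
#' @examples
#' scanCBlock("CAACAAAAAACAAAC")
#' @export
scanCBlock <- function(seq) {
  chars <- .seqChars(seq)
  n <- length(chars)
  out <- data.frame(start = integer(0), end = integer(0))
  if (n < 15L) return(out)
  starts <- seq_len(n - 14L)
  hit <- chars[starts] == "C" & chars[starts + 3L] == "C" &
    chars[starts + 10L] == "C" & chars[starts + 14L] == "C"
  if (any(hit)) {
    out <- data.frame(start = starts[hit], end = starts[hit] + 14L)
  }
  out
}

#' Scan for the leucine-zipper-like block
#'
#' Searches for the anchor frame `[LVI] X6 [LVI] X3 [LVI] X6 [LVI]` (anchor
#' count and alphabet set by the grammar) at or after `search_from`.
#' Complete frames (all anchors hydrophobic) are preferred; if none exists,
#' the first frame matching at least `min_partial_anchors` anchors is
#' returned as incomplete.
#'
#' @param seq protein sequence.
#' @param search_from 1-based position to start searching at.
#' @param grammar a [MotifGrammar-class].
#' @return list with `span` (integer start/end or NULL), `complete`
#'   (logical) and `n_anchors` (matched anchor count), or NULL when no
#'   frame is found.
#' @examples
#' scanZipper("LAAAAAALAAALAAAAAAL")
#' scanZipper("LAAAAAALAAAKAAAAAAL")  # third anchor K: incomplete
#' @export
scanZipper <- function(seq, search_from = 1L, grammar = motifGrammar()) {
  chars <- .seqChars(seq)
  n <- length(chars)
  off <- .zipperOffsets(grammar@n_zipper_anchors)
  w <- off[length(off)] + 1L
  if (search_from < 1L || search_from > n) {
    stop("search_from must lie within the sequence")
  }
  if (n - search_from + 1L < w) return(NULL)
  alpha <- strsplit(grammar@zipper_alphabet, "", fixed = TRUE)[[1]]
  starts <- search_from:(n - w + 1L)
  counts <- integer(length(starts))
  for (o in off) {
    counts <- counts + (chars[starts + o] %in% alpha)
  }
  full <- which(counts == grammar@n_zipper_anchors)
  if (length(full)) {
    s <- starts[full[1]]
    return(list(span = c(s, s + w - 1L), complete = TRUE,
                n_anchors = grammar@n_zipper_anchors))
  }
  partial <- which(counts >= grammar@min_partial_anchors)
  if (length(partial)) {
    s <- starts[partial[1]]
    return(list(span = c(s, s + w - 1L), complete = FALSE,
                n_anchors = counts[partial[1]]))
  }
  NULL
}

#' Scan for the GAS block
#'
#' Locates anchor1 (`F X2 [VA] H`) at or after `from`, then anchor2
#' (`D P [VI] Y G`) strictly downstream. The proline and glycine of anchor2
#' are always required; under a relaxed grammar (`gas_strict = FALSE`) the
#' D, [VI] and Y positions accept any residue. Flags report whether each
#' anchor matched the strict pattern.
#'
#' @param seq protein sequence.
#' @param from 1-based position at which the search starts (typically just
#'   after a located C-block).
#' @param grammar a [MotifGrammar-class].
#' @return list with `span` (anchor1 start to anchor2 end), `anchor1_strict`,
#'   `anchor2_strict`, or NULL when not found.
#' @examples
#' scanGasBlock("AAFAAVHAAADPVYGAA")
#' @export
scanGasBlock <- function(seq, from = 1L, grammar = motifGrammar()) {
  chars <- .seqChars(seq)
  n <- length(chars)
  if (from < 1L) from <- 1L
  if (n - from + 1L < 10L) return(NULL)
  a1_starts <- from:(n - 9L)
  a1 <- chars[a1_starts] == "F" & chars[a1_starts + 3L] %in% c("V", "A") &
    chars[a1_starts + 4L] == "H"
  for (i in a1_starts[a1]) {
    j_starts <- (i + 5L):(n - 4L)
    if (length(j_starts) == 0L || j_starts[1] > n - 4L) next
    strict <- chars[j_starts] == "D" & chars[j_starts + 1L] == "P" &
      chars[j_starts + 2L] %in% c("V", "I") & chars[j_starts + 3L] == "Y" &
      chars[j_starts + 4L] == "G"
    relaxed <- chars[j_starts + 1L] == "P" & chars[j_starts + 4L] == "G"
    cand <- if (grammar@gas_strict) strict else (strict | relaxed)
    if (any(cand)) {
      j <- j_starts[which(cand)[1]]
      return(list(span = c(i, j + 4L),
                  anchor1_strict = TRUE,
                  anchor2_strict = unname(strict[which(j_starts == j)])))
    }
  }
  NULL
}

#' Classify a protein into LBD Class I / Class II / none
#'
#' Applies the three-block LOB-domain grammar: Class I requires a C-block
#' followed (within the grammar's gap limits) by a complete zipper; Class II
#' requires a C-block with no complete downstream zipper (an incomplete
#' frame or none at all); sequences without a C-block are "none". Among
#' multiple C-blocks the earliest one admitting a full downstream grammar
#' match is chosen.
#'
#' @param seq protein sequence (character or `AAString`).
#' @param grammar a [MotifGrammar-class].
#' @return A [LobDomainAnnotation-class].
#' @examples
#' p <- paste0("CAACAAAAAACAAAC", "AAAA", "FAAVHAAADPVYG", "AAAA",
#'             "LAAAAAALAAALAAAAAAL")
#' classCall(classifyProtein(p))
#' @export
classifyProtein <- function(seq, grammar = motifGrammar()) {
  cb <- scanCBlock(seq)
  none <- new("LobDomainAnnotation",
              c_block_span = c(NA_integer_, NA_integer_),
              gas_span = c(NA_integer_, NA_integer_),
              zipper_span = c(NA_integer_, NA_integer_),
              zipper_complete = FALSE, zipper_anchors = 0L,
              gas_anchor1_strict = NA, gas_anchor2_strict = NA,
              class_call = "none")
  if (nrow(cb) == 0L) return(none)
  n <- nchar(if (methods::is(seq, "XString")) as.character(seq) else seq)

  annotateFrom <- function(k) {
    c_span <- c(cb$start[k], cb$end[k])
    gas <- scanGasBlock(seq, from = c_span[2] + 1L, grammar = grammar)
    if (!is.null(gas) &&
        gas$span[1] - (c_span[2] + 1L) > grammar@max_gap_cblock_to_gas) {
      gas <- NULL
    }
    zfrom <- if (!is.null(gas)) gas$span[2] + 1L else c_span[2] + 1L
    zlimit <- if (!is.null(gas)) grammar@max_gap_gas_to_zipper else
      grammar@max_gap_cblock_to_gas + grammar@max_gap_gas_to_zipper
    zip <- if (zfrom <= n) scanZipper(seq, search_from = zfrom,
                                      grammar = grammar) else NULL
    if (!is.null(zip) && zip$span[1] - zfrom > zlimit) zip <- NULL
    list(c_span = c_span, gas = gas, zip = zip)
  }

  # Prefer the earliest C-block yielding Class I; fall back to the first.
  chosen <- NULL
  for (k in seq_len(nrow(cb))) {
    a <- annotateFrom(k)
    if (!is.null(a$zip) && isTRUE(a$zip$complete)) {
      chosen <- a
      break
    }
    if (is.null(chosen)) chosen <- a
  }
  a <- chosen
  cls <- if (!is.null(a$zip) && isTRUE(a$zip$complete)) "I" else "II"
  new("LobDomainAnnotation",
      c_block_span = as.integer(a$c_span),
      gas_span = if (is.null(a$gas)) c(NA_integer_, NA_integer_) else
        as.integer(a$gas$span),
      zipper_span = if (is.null(a$zip)) c(NA_integer_, NA_integer_) else
        as.integer(a$zip$span),
      zipper_complete = if (is.null(a$zip)) FALSE else a$zip$complete,
      zipper_anchors = if (is.null(a$zip)) 0L else as.integer(a$zip$n_anchors),
      gas_anchor1_strict = if (is.null(a$gas)) NA else a$gas$anchor1_strict,
      gas_anchor2_strict = if (is.null(a$gas)) NA else a$gas$anchor2_strict,
      class_call = cls)
}

#' Annotate a whole proteome
#'
#' Vectorized wrapper around [classifyProtein()].
#'
#' @param proteins named character vector or `AAStringSet`.
#' @param grammar a [MotifGrammar-class].
#' @return data.frame with one row per sequence: block spans, zipper
#'   completeness and anchor count, GAS anchor flags, and the `class` call.
#' @export
annotateProteome <- function(proteins, grammar = motifGrammar()) {
  if (methods::is(proteins, "XStringSet")) proteins <- as.character(proteins)
  ids <- names(proteins)
  if (is.null(ids)) ids <- paste0("seq", seq_along(proteins))
  rows <- lapply(seq_along(proteins), function(i) {
    a <- classifyProtein(proteins[[i]], grammar)
    data.frame(id = ids[i],
               c_block_start = a@c_block_span[1], c_block_end = a@c_block_span[2],
               gas_start = a@gas_span[1], gas_end = a@gas_span[2],
               zipper_start = a@zipper_span[1], zipper_end = a@zipper_span[2],
               zipper_complete = a@zipper_complete,
               zipper_anchors = a@zipper_anchors,
               class = a@class_call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Find conserved blocks in a subfamily alignment
#'
#' Reports maximal runs of alignment columns, at least `min_len` columns
#' long, in which the majority residue reaches the conservation threshold.
#' Gaps are excluded from the numerator but kept in the denominator, so a
#' column must be conserved across the whole membership, gapped rows
#' included.
#'
#' @param msa aligned proteins (`AAStringSet`, character vector of equal
#'   lengths, or character matrix); at least 2 rows.
#' @param min_len minimum block length in columns (default 10).
#' @param min_conservation minimum per-column majority-residue fraction
#'   (default 0.5, inclusive).
#' @return data.frame with columns `start`, `end`, `length`,
#'   `mean_conservation`.
#' @examples
#' aln <- c(a = "AAAAAAAAAAAA", b = "AAAAAAAAAAAA",
#'          c = "AAAAAAAAAAAA", d = "CCCCCCCCCCCC")
#' findConservedBlocks(aln, min_len = 10, min_conservation = 0.5)
#' @export
findConservedBlocks <- function(msa, min_len = 10L, min_conservation = 0.5) {
  m <- asMsaMatrix(msa)
  if (nrow(m) < 2L) stop("need at least 2 aligned sequences")
  cons <- apply(m, 2L, function(col) {
    res <- col[!col %in% c("-", ".")]
    if (length(res) == 0L) return(0)
    max(table(res)) / length(col)
  })
  keep <- cons >= min_conservation
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values & r$lengths >= min_len)
  data.frame(start = starts[idx], end = ends[idx],
             length = r$lengths[idx],
             mean_conservation = vapply(idx, function(i) {
               mean(cons[starts[i]:ends[i]])
             }, numeric(1)))
}
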