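# Promoter extraction with no-ORF truncation, IUPAC cis-element scanning on
# both strands, hypergeometric enrichment against a background set, and
# enumerative k-mer discovery.
#
# Coordinates are 1-based inclusive externally; reported motif positions
# are relative to the plus-strand promoter sequence as returned.

#' Load the bundled cis-element dictionary
#'
#' A curated set of named plant cis-regulatory elements (hormone, light,
#' stress and tissue-specificity related) with IUPAC patterns compiled
#' from the public promoter-element literature. The dictionary is data:
#' users may supply their own table with the same columns.
#'
#' @param path optional path to a tab-delimited motif table with columns
#'   `name`, `pattern`, `category`; defaults to the bundled dictionary.
#' @return data.frame of motif definitions.
#' @export
loadMotifDictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_motifs.tsv", package = "lbdfam")
  }
  mot <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "pattern", "category") %in% names(mot)))
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", mot$pattern)
  if (any(bad)) {
    stop("non-IUPAC pattern(s): ", paste(mot$name[bad], collapse = ", "))
  }
  mot
}

#' Extract promoter windows from a genome
#'
#' Returns the `window` bp upstream of the translation start of each gene,
#' on the coding strand (reverse-complemented for minus-strand genes).
#' With `noorf = TRUE` the window is truncated at the nearest upstream
#' annotated gene boundary so that no neighbouring ORF is included. Genes
#' near a contig edge yield a shorter sequence, flagged, not an error.
#'
#' @param genome named `DNAStringSet` (one sequence per chromosome; names
#'   must match the catalog's chromosome labels).
#' @param catalog data.frame with `locus_id`, `chromosome`, `strand`,
#'   `start`, `end` (e.g. from [parseLocusTable()] or
#'   [generateGeneModels()]).
#' @param window upstream window in bp (1500, 3000 and 2500 are the usual
#'   presets).
#' @param noorf truncate at the nearest upstream gene boundary.
#' @return list with `sequences` (`DNAStringSet` named by locus_id),
#'   `info` (data.frame `locus_id`, `length`, `truncated`, `at_edge`).
#' @export
extractPromoters <- function(genome, catalog, window = 1500L,
                             noorf = FALSE) {
  chroms <- unique(catalog$chromosome)
  keymap <- names(genome)
  missing_chr <- setdiff(chroms, keymap)
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  seqs <- character(nrow(catalog))
  info <- data.frame(locus_id = catalog$locus_id,
                     length = 0L, truncated = FALSE, at_edge = FALSE,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(catalog))) {
    chr <- catalog$chromosome[i]
    chrlen <- Biostrings::width(genome[chr])
    plus <- catalog$strand[i] == "+"
    if (plus) {
      to <- catalog$start[i] - 1L
      from <- catalog$start[i] - window
    } else {
      from <- catalog$end[i] + 1L
      to <- catalog$end[i] + window
    }
    if (from < 1L) { from <- 1L; info$at_edge[i] <- TRUE }
    if (to > chrlen) { to <- chrlen; info$at_edge[i] <- TRUE }
    if (noorf) {
      others <- catalog[-i, , drop = FALSE]
      others <- others[others$chromosome == chr, , drop = FALSE]
      if (plus) {
        ends <- others$end[others$end < catalog$start[i]]
        if (length(ends) && max(ends) + 1L > from) {
          from <- max(ends) + 1L
          info$truncated[i] <- TRUE
        }
      } else {
        starts <- others$start[others$start > catalog$end[i]]
        if (length(starts) && min(starts) - 1L < to) {
          to <- min(starts) - 1L
          info$truncated[i] <- TRUE
        }
      }
    }
    if (to < from) {
      seqs[i] <- ""
      next
    }
    s <- Biostrings::subseq(genome[[chr]], from, to)
    if (!plus) s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  info$length <- nchar(seqs)
  out <- Biostrings::DNAStringSet(setNames(seqs, catalog$locus_id))
  list(sequences = out, info = info)
}

#' Scan a promoter for an IUPAC motif
#'
#' Reports every position where all IUPAC classes of the pattern match;
#' with `both_strands` the reverse complement of the pattern is also
#' scanned and its hits are reported in plus-strand coordinates.
#'
#' @param promoter DNA sequence (character or `DNAString`).
#' @param motif pattern string (IUPAC codes) or a one-row motif definition
#'   with a `pattern` column.
#' @param both_strands scan both strands (default TRUE).
#' @return data.frame with columns `start`, `end` (1-based) and `strand`.
#' @examples
#' scanMotif("AAACGTGAA", "ACGTG", both_strands = FALSE)
#' @export
scanMotif <- function(promoter, motif, both_strands = TRUE) {
  pattern <- if (is.list(motif) || is.data.frame(motif)) motif$pattern else motif
  if (methods::is(promoter, "XString")) {
    subject <- promoter
  } else {
    subject <- Biostrings::DNAString(promoter)
  }
  pat <- Biostrings::DNAString(pattern)
  hitsOne <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subject, fixed = FALSE)
    if (length(m) == 0L) {
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0)))
    }
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m),
               strand = strand, stringsAsFactors = FALSE)
  }
  out <- hitsOne(pat, "+")
  if (both_strands) {
    rc <- Biostrings::reverseComplement(pat)
    minus <- hitsOne(rc, "-")
    # a palindromic pattern would duplicate plus hits; keep both strands'
    # reports distinct as scanning semantics, ordered by position
    out <- rbind(out, minus)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.presence <- function(promoters, pattern, both_strands = TRUE) {
  vapply(seq_along(promoters), function(i) {
    nrow(scanMotif(promoters[[i]], pattern, both_strands)) > 0L
  }, logical(1))
}

#' Cis-element enrichment of target vs background promoters
#'
#' The unit is presence/absence per promoter (robust to length
#' differences): for each motif, a one-sided hypergeometric upper-tail
#' p-value tests over-representation of promoters containing the motif
#' among targets within targets + background. Raw p-values are reported by
#' default (flagging rows with p < alpha); Benjamini-Hochberg adjustment
#' is available.
#'
#' @param targets,background promoter sets (`DNAStringSet` or the list
#'   returned by [extractPromoters()]); gene sets must be disjoint.
#' @param motifs motif definition data.frame (default: bundled
#'   dictionary).
#' @param alpha enrichment call threshold on the (possibly adjusted)
#'   p-value (default 0.01).
#' @param adjust "none" (default, raw p-values) or "BH".
#' @param both_strands scan both strands.
#' @return data.frame with one row per motif: `motif`, `n_target_with`,
#'   `n_target`, `n_background_with`, `n_background`, `p_value`,
#'   `enriched`.
#' @export
motifEnrichment <- function(targets, background,
                            motifs = loadMotifDictionary(),
                            alpha = 0.01, adjust = c("none", "BH"),
                            both_strands = TRUE) {
  adjust <- match.arg(adjust)
  if (is.list(targets) && !is.null(targets$sequences)) targets <- targets$sequences
  if (is.list(background) && !is.null(background$sequences)) {
    background <- background$sequences
  }
  if (length(background) == 0L) stop("empty background set")
  shared <- intersect(names(targets), names(background))
  if (length(shared)) {
    stop("target and background gene sets must be disjoint: ",
         paste(shared, collapse = ", "))
  }
  nt <- length(targets); nb <- length(background)
  rows <- lapply(seq_len(nrow(motifs)), function(k) {
    pt <- sum(.presence(targets, motifs$pattern[k], both_strands))
    pb <- sum(.presence(background, motifs$pattern[k], both_strands))
    p <- stats::phyper(pt - 1, pt + pb, nt + nb - pt - pb, nt,
                       lower.tail = FALSE)
    data.frame(motif = motifs$name[k], n_target_with = pt, n_target = nt,
               n_background_with = pb, n_background = nb,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$enriched <- out$p_value < alpha
  out[order(out$p_value, out$motif), , drop = FALSE]
}

.revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Enumerative k-mer discovery
#'
#' Enumerates every k-mer present in the promoters for each k in
#' `k_range`, merges reverse-complement pairs under the lexicographically
#' smaller representative, and ranks k-mers by the hypergeometric
#' upper-tail p-value of their presence among targets vs background. A
#' transparent stand-in for de-novo motif search.
#'
#' @param targets,background promoter sets.
#' @param k_range integer vector of k values (default 6:12); values larger
#'   than every sequence contribute nothing.
#' @param top_n rows to return (default 50; Inf for all).
#' @return data.frame ranked ascending by p-value: `kmer`, `k`,
#'   `n_target_with`, `n_background_with`, `p_value`.
#' @export
kmerDiscovery <- function(targets, background, k_range = 6:12, top_n = 50L) {
  if (is.list(targets) && !is.null(targets$sequences)) targets <- targets$sequences
  if (is.list(background) && !is.null(background$sequences)) {
    background <- background$sequences
  }
  nt <- length(targets); nb <- length(background)
  seqKmers <- function(seq, k) {
    s <- as.character(seq)
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- unique(substring(s, 1:(n - k + 1L), k:n))
    km <- km[!grepl("[^ACGT]", km)]
    if (length(km) == 0L) return(character(0))
    unique(pmin(km, .revcompChar(km)))
  }
  rows <- list()
  for (k in k_range) {
    tl <- lapply(seq_along(targets), function(i) seqKmers(targets[[i]], k))
    bl <- lapply(seq_along(background), function(i) seqKmers(background[[i]], k))
    all_km <- unique(c(unlist(tl), unlist(bl)))
    if (length(all_km) == 0L) next
    tc <- table(factor(unlist(tl), levels = all_km))
    bc <- table(factor(unlist(bl), levels = all_km))
    p <- stats::phyper(as.integer(tc) - 1L, as.integer(tc) + as.integer(bc),
                       nt + nb - as.integer(tc) - as.integer(bc), nt,
                       lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      kmer = all_km, k = k,
      n_target_with = as.integer(tc), n_background_with = as.integer(bc),
      p_value = p, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(kmer = character(0), k = integer(0),
                      n_target_with = integer(0),
                      n_background_with = integer(0), p_value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_n)
}
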