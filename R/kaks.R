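# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Site counting: at each codon position the three possible single-nucleotide
# changes are classified; the synonymous fraction of that position is
# n_syn / 3. Changes creating a stop codon count as nonsynonymous, so every
# codon contributes exactly 3 sites (Ns + Ss = 3 per codon). Substitution
# counting for codons differing at several positions averages the
# synonymous/nonsynonymous step classification over all mutational pathways
# (orders of the differing positions), excluding pathways that pass through
# a stop codon (falling back to all pathways if every one is blocked).

.NT <- c("T", "C", "A", "G")

.codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.isStop <- function(codon, code) code[[codon]] == "*"

# synonymous site count of one codon (0..3)
.synSites <- function(codon, code) {
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(.NT, chars[pos])) {
      mut <- chars
      mut[pos] <- nt
      mutc <- paste(mut, collapse = "")
      if (code[[mutc]] == aa && code[[mutc]] != "*") s <- s + 1 / 3
      # changes to stop codons count as nonsynonymous (site total stays 3)
    }
  }
  s
}

# average (syn, nonsyn) substitutions between two codons, pathway-averaged
.codonSubs <- function(c1, c2, code) {
  ch1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  ch2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  diff_pos <- which(ch1 != ch2)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(diff_pos) else {
    if (nd == 2L) list(diff_pos, rev(diff_pos)) else {
      perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(perms3, function(o) diff_pos[o])
    }
  }
  tallies <- list()
  for (order_ in perms) {
    cur <- ch1
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (pos in order_) {
      prev <- paste(cur, collapse = "")
      cur[pos] <- ch2[pos]
      nxt <- paste(cur, collapse = "")
      if (code[[nxt]] == "*" && nxt != c2) {
        blocked <- TRUE
        break
      }
      if (code[[prev]] == code[[nxt]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
    }
    if (!blocked) tallies[[length(tallies) + 1L]] <- c(syn, nonsyn)
  }
  if (length(tallies) == 0L) {
    # every pathway passes through a stop: average over all of them
    for (order_ in perms) {
      cur <- ch1
      syn <- 0; nonsyn <- 0
      for (pos in order_) {
        prev <- paste(cur, collapse = "")
        cur[pos] <- ch2[pos]
        nxt <- paste(cur, collapse = "")
        if (code[[prev]] == code[[nxt]]) syn <- syn + 1 else
          nonsyn <- nonsyn + 1
      }
      tallies[[length(tallies) + 1L]] <- c(syn, nonsyn)
    }
  }
  avg <- Reduce(`+`, tallies) / length(tallies)
  c(syn = avg[1], nonsyn = avg[2])
}

.splitCodons <- function(cds) {
  if (methods::is(cds, "XString")) cds <- as.character(cds)
  cds <- toupper(gsub("U", "T", cds))
  if (nchar(cds) %% 3 != 0) stop("CDS length must be a multiple of 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Nei-Gojobori (1986) Ka/Ks for a codon-aligned CDS pair
#'
#' Counts synonymous and nonsynonymous sites (averaged over both
#' sequences) and substitutions (pathway-averaged for multi-hit codons),
#' then applies the Jukes-Cantor correction d = -3/4 ln(1 - 4p/3) to both
#' proportions. Ka/Ks >> 1 indicates positive selection; the ratio is NA
#' when Ks = 0.
#'
#' @param cds_a,cds_b in-frame coding sequences of equal length (multiple
#'   of 3, no internal stop codons).
#' @return list with `ka`, `ks`, `ratio`, and the intermediate counts
#'   `n_sites`, `s_sites`, `n_subs`, `s_subs`, `pn`, `ps`.
#' @examples
#' kaksNG86("TTTGGG", "TTCGGG")  # synonymous third-position change
#' @export
kaksNG86 <- function(cds_a, cds_b) {
  code <- .codonTable()
  ca <- .splitCodons(cds_a)
  cb <- .splitCodons(cds_b)
  if (length(ca) != length(cb)) stop("CDS length mismatch")
  bad <- c(ca, cb)[!c(ca, cb) %in% names(code)]
  if (length(bad)) stop("non-ACGT codon(s): ", paste(unique(bad), collapse = ", "))
  internal_a <- ca[-length(ca)]
  internal_b <- cb[-length(cb)]
  if (any(vapply(internal_a, .isStop, logical(1), code = code)) ||
      any(vapply(internal_b, .isStop, logical(1), code = code))) {
    stop("internal stop codon in CDS")
  }
  Sa <- sum(vapply(ca, .synSites, numeric(1), code = code))
  Sb <- sum(vapply(cb, .synSites, numeric(1), code = code))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  subs <- mapply(function(x, y) .codonSubs(x, y, code), ca, cb)
  Sd <- sum(subs["syn", ])
  Nd <- sum(subs["nonsyn", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)  # correction undefined, saturated
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps)
  ka <- jc(pn)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  list(ka = ka, ks = ks, ratio = ratio,
       n_sites = N, s_sites = S, n_subs = Nd, s_subs = Sd,
       pn = pn, ps = ps)
}
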