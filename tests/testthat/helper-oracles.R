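# Independent oracles used by the test suite. These deliberately use
# different machinery (regex engine, recursive enumeration) than the
# package implementations they check.

table1Path <- function() {
  system.file("extdata", "table1_vvilbd.tsv", package = "lbdfam")
}

# C-block oracle: overlapping matches via a PCRE lookahead.
oracleCBlockStarts <- function(seq) {
  m <- gregexpr("(?=(C.{2}C.{6}C.{3}C))", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Complete-zipper oracle: first full [LVI]-anchored frame at/after `from`.
oracleZipperStart <- function(seq, from = 1L) {
  sub <- substring(seq, from)
  m <- regexpr("(?=([LVI].{6}[LVI].{3}[LVI].{6}[LVI]))", sub, perl = TRUE)
  if (m[1] == -1L) NA_integer_ else as.integer(m) + from - 1L
}

# conserved-column oracle: explicit per-column majority computation,
# followed by a run scan written as a plain loop.
oracleConservedBlocks <- function(rows, min_len, min_cons) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ok <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col[col != "-" & col != "."]
    ok[j] <- length(res) > 0 && max(tabulate(factor(res))) / nrow(m) >= min_cons
  }
  blocks <- list()
  j <- 1L
  while (j <= length(ok)) {
    if (ok[j]) {
      k <- j
      while (k < length(ok) && ok[k + 1L]) k <- k + 1L
      if (k - j + 1L >= min_len) {
        blocks[[length(blocks) + 1L]] <- c(start = j, end = k)
      }
      j <- k + 1L
    } else j <- j + 1L
  }
  blocks
}

# NG86 oracle: per-codon site counts and pathway-averaged substitution
# counts via recursive enumeration (implementation uses explicit
# permutation lists instead).
.oracleCode <- as.character(Biostrings::GENETIC_CODE)
names(.oracleCode) <- names(Biostrings::GENETIC_CODE)

oracleSynSites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- .oracleCode[[codon]]
  tot <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      mut <- ch; mut[p] <- b
      maa <- .oracleCode[[paste(mut, collapse = "")]]
      if (maa == aa && maa != "*") tot <- tot + 1 / 3
    }
  }
  tot
}

oracleCodonSubs <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  pos <- which(ch1 != ch2)
  if (!length(pos)) return(c(0, 0))
  paths <- list()
  recurse <- function(cur, remaining, syn, nonsyn, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- list(counts = c(syn, nonsyn),
                                           blocked = blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- ch2[p]
      nxtc <- paste(nxt, collapse = "")
      curc <- paste(cur, collapse = "")
      step_syn <- .oracleCode[[curc]] == .oracleCode[[nxtc]]
      step_blocked <- blocked ||
        (.oracleCode[[nxtc]] == "*" && nxtc != c2)
      recurse(nxt, setdiff(remaining, p),
              syn + as.numeric(step_syn), nonsyn + as.numeric(!step_syn),
              step_blocked)
    }
  }
  recurse(ch1, pos, 0, 0, FALSE)
  open <- Filter(function(p) !p$blocked, paths)
  use <- if (length(open)) open else paths
  Reduce(`+`, lapply(use, `[[`, "counts")) / length(use)
}

# random stop-free CDS of n codons
randomCDS <- function(n_codons) {
  codons <- names(.oracleCode)[.oracleCode != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

mutateCDS <- function(cds, n_changes) {
  ch <- strsplit(cds, "")[[1]]
  repeat {
    out <- ch
    pos <- sample(length(ch), n_changes)
    for (p in pos) out[p] <- sample(setdiff(c("A", "C", "G", "T"), out[p]), 1)
    s <- paste(out, collapse = "")
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (!any(.oracleCode[cods] == "*")) return(s)
  }
}
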