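# Internal helpers shared across modules.

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# The 20 standard amino acids.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residues that cannot instantiate any LOB-domain anchor (no C, F, L, V, I).
# Used as the background alphabet of the protein generator so that planted
# blocks are the only blocks (see the methods vignette).
AA_SAFE <- setdiff(AA20, c("C", "F", "L", "V", "I"))

randomResidues <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Coerce an alignment (AAStringSet / character vector / character matrix)
# to a character matrix of single residues, one row per sequence.
asMsaMatrix <- function(msa) {
  if (is.matrix(msa) && is.character(msa)) {
    return(msa)
  }
  if (methods::is(msa, "XStringSet")) {
    msa <- as.character(msa)
  }
  if (!is.character(msa)) {
    stop("alignment must be an AAStringSet, character vector or character matrix")
  }
  if (length(unique(nchar(msa))) != 1L) {
    stop("ragged alignment: all rows must have equal length")
  }
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

msaMatrixToSet <- function(m, class = "AAStringSet") {
  x <- apply(m, 1L, paste, collapse = "")
  out <- switch(class,
    AAStringSet = Biostrings::AAStringSet(x),
    DNAStringSet = Biostrings::DNAStringSet(x),
    stop("unsupported set class"))
  names(out) <- rownames(m)
  out
}

# Deterministic sub-seed derivation (kept well below 2^31).
subSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
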