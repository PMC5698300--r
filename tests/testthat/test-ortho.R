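test_that("local alignment hits behave on identical and unrelated pairs", {
  withr::with_seed(42, {
    a <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                      200, TRUE), collapse = "")
    hits <- allVsAllHits(c(x = a), c(y = a))
    expect_equal(hits$identity, 1.0)
    expect_equal(hits$aln_len, 200L)
    expect_lt(hits$e_value, 1e-20)
    # unrelated random pairs never reach the e-value threshold
    emin <- Inf
    for (i in 1:20) {
      r1 <- paste(sample(lbdfam:::AA20, 200, TRUE), collapse = "")
      r2 <- paste(sample(lbdfam:::AA20, 200, TRUE), collapse = "")
      h <- allVsAllHits(c(q = r1), c(s = r2))
      emin <- min(emin, h$e_value)
    }
    expect_gt(emin, 1e-10)
  })
  expect_error(allVsAllHits(Biostrings::AAStringSet(), c(a = "AA")), "nonempty")
  expect_error(allVsAllHits(c(a = "A!A"), c(b = "AAA")), "illegal")
})

test_that("local alignment score equals a brute-force DP oracle", {
  # exhaustive Smith-Waterman with linear-ish gap model matching
  # gapOpening + gapExtension per additional position
  swOracle <- function(s1, s2, mat, go, ge) {
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    n <- length(a); m <- length(b)
    H <- matrix(0, n + 1, m + 1)
    E <- matrix(-Inf, n + 1, m + 1)  # gap in s2 (vertical)
    F <- matrix(-Inf, n + 1, m + 1)
    best <- 0
    for (i in 2:(n + 1)) {
      for (j in 2:(m + 1)) {
        E[i, j] <- max(H[i - 1, j] - go - ge, E[i - 1, j] - ge)
        F[i, j] <- max(H[i, j - 1] - go - ge, F[i, j - 1] - ge)
        H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]],
                       E[i, j], F[i, j])
        best <- max(best, H[i, j])
      }
    }
    best
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  withr::with_seed(7, {
    for (k in 1:5) {
      s1 <- paste(sample(lbdfam:::AA20, 12, TRUE), collapse = "")
      s2 <- paste(sample(lbdfam:::AA20, 15, TRUE), collapse = "")
      got <- allVsAllHits(c(a = s1), c(b = s2))$score
      want <- swOracle(s1, s2, BLOSUM62, 11, 1)
      expect_equal(got, want)
    }
  })
})

test_that("retention filter applies strict inequalities", {
  hits <- data.frame(query = "a", subject = c("x", "y", "z"),
                     score = 100, identity = c(0.41, 0.40, 0.90),
                     aln_len = 100, e_value = c(1e-25, 1e-25, 1e-19))
  kept <- retainHits(hits)
  expect_identical(kept$subject, "x")  # 0.40 dropped (strict >), 1e-19 dropped
  # boundary e-value exactly at the ceiling is dropped
  hits$e_value <- 1e-20
  expect_equal(nrow(retainHits(hits)), 0L)
  # monotonicity: tightening thresholds never adds hits
  hits2 <- data.frame(query = rep("a", 50), subject = paste0("s", 1:50),
                      score = 1:50, identity = runif(50), aln_len = 100,
                      e_value = 10^-runif(50, 10, 30))
  loose <- retainHits(hits2, e_max = 1e-15, identity_min = 0.3)
  tight <- retainHits(hits2, e_max = 1e-20, identity_min = 0.5)
  expect_true(all(tight$subject %in% loose$subject))
})

test_that("reciprocal best hits equal a brute-force check on toy tables", {
  mk <- function(q, s, sc) data.frame(query = q, subject = s, score = sc,
                                      identity = 0.9, aln_len = 100,
                                      e_value = 1e-30)
  ab <- mk(rep(c("A1", "A2", "A3"), each = 3), rep(c("B1", "B2", "B3"), 3),
           c(9, 2, 1, 3, 8, 1, 2, 3, 7))
  ba <- mk(rep(c("B1", "B2", "B3"), each = 3), rep(c("A1", "A2", "A3"), 3),
           c(9, 3, 2, 2, 8, 3, 1, 1, 7))
  got <- reciprocalBestHits(ab, ba)
  # brute force: best of each row/column
  bestAB <- tapply(seq_len(nrow(ab)), ab$query, function(i) {
    ab$subject[i][which.max(ab$score[i])]
  })
  bestBA <- tapply(seq_len(nrow(ba)), ba$query, function(i) {
    ba$subject[i][which.max(ba$score[i])]
  })
  want <- sort(names(bestAB)[bestBA[bestAB[names(bestAB)]] == names(bestAB)])
  expect_identical(got$a, want)
  expect_identical(got$b, as.vector(bestAB[got$a]))
  # A's best is B but B's best is A' -> no pair
  ba2 <- mk(rep(c("B1", "B2", "B3"), each = 3), rep(c("A1", "A2", "A3"), 3),
            c(1, 9, 2, 2, 8, 3, 1, 1, 7))
  got2 <- reciprocalBestHits(ab, ba2)
  expect_false("A1" %in% got2$a)
  # symmetry: swapping roles swaps the columns
  sw <- reciprocalBestHits(ba, ab)
  expect_setequal(paste(got$a, got$b), paste(sw$b, sw$a))
})

test_that("synthetic families are fully recovered without loss/duplication", {
  cfg <- simConfig(seed = 31, loss_prob = 0, dup_prob = 0,
                   mutation_rate = 0.03)
  fam <- generateOrthologFamilies(cfg)
  om <- orthologPresenceMatrix(fam$vitis, fam$species)
  merged <- merge(om$results, fam$truth, by = c("gene", "species"))
  expect_true(all(merged$category.x == "one_to_one"))
  expect_true(all(merged$category.y == "one_to_one"))
})

test_that("planted duplications break reciprocity; losses give no match", {
  cfg <- simConfig(seed = 32, n_genes = 10L, n_species = 1L,
                   loss_prob = 0, dup_prob = 0.5, mutation_rate = 0.03)
  fam <- generateOrthologFamilies(cfg)
  expect_true(any(fam$truth$category == "homolog_only"))
  om <- orthologPresenceMatrix(fam$vitis, fam$species)
  merged <- merge(om$results, fam$truth, by = c("gene", "species"))
  expect_identical(merged$category.x, merged$category.y)
  # total loss
  cfgL <- simConfig(seed = 33, n_genes = 6L, n_species = 2L, loss_prob = 1)
  famL <- generateOrthologFamilies(cfgL)
  expect_true(all(famL$truth$category == "no_match"))
  expect_equal(sum(vapply(famL$species, length, integer(1))), 0L)
})

test_that("NG86 handles identical and synonymous-only pairs", {
  r <- kaksNG86("ATGAAACCC", "ATGAAACCC")
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(is.na(r$ratio))
  # TTT -> TTC is synonymous (Phe)
  r2 <- kaksNG86("TTTGGG", "TTCGGG")
  expect_equal(r2$pn, 0)
  expect_gt(r2$ps, 0)
  expect_equal(r2$n_subs, 0)
  expect_equal(r2$s_subs, 1)
  expect_error(kaksNG86("ATG", "ATGAAA"), "mismatch")
  expect_error(kaksNG86("ATGTAAAAA", "ATGTACAAA"), "stop")
  expect_error(kaksNG86("ATGA", "ATGA"), "multiple of 3")
})

test_that("NG86 sites and substitutions equal the enumeration oracle", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      a <- randomCDS(30)
      b <- mutateCDS(a, sample(3:12, 1))
      got <- kaksNG86(a, b)
      ca <- substring(a, seq(1, 90, 3), seq(3, 90, 3))
      cb <- substring(b, seq(1, 90, 3), seq(3, 90, 3))
      S_or <- (sum(vapply(ca, oracleSynSites, numeric(1))) +
                 sum(vapply(cb, oracleSynSites, numeric(1)))) / 2
      subs <- mapply(oracleCodonSubs, ca, cb)
      expect_equal(got$s_sites, S_or)
      expect_equal(got$n_sites + got$s_sites, 90)  # 3 sites per codon
      expect_equal(got$s_subs, sum(subs[1, ]))
      expect_equal(got$n_subs, sum(subs[2, ]))
      expect_equal(got$ps, sum(subs[1, ]) / S_or)
    }
  })
})
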