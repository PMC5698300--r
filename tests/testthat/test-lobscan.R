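test_that("C-block scanning matches constructed and negative examples", {
  hit <- scanCBlock("CAACAAAAAACAAAC")
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end), c(1L, 15L))
  expect_equal(nrow(scanCBlock("AAAAAAAAAA")), 0L)
  expect_equal(nrow(scanCBlock("")), 0L)
  # X is tolerated but never matches a C anchor
  expect_equal(nrow(scanCBlock("XAACAAAAAACAAAC")), 0L)
  expect_equal(nrow(scanCBlock("CXXCXXXXXXCXXXC")), 1L)
})

test_that("C-block scanning equals the regex oracle on random sequences", {
  withr::with_seed(101, {
    total <- 0L
    for (i in 1:100) {
      s <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                        200, replace = TRUE), collapse = "")
      got <- scanCBlock(s)$start
      expect_identical(got, oracleCBlockStarts(s))
      total <- total + length(got)
    }
    # per-position match probability is (1/20)^4; binomial sanity bound
    n_pos <- 100 * (200 - 14)
    expect_lte(total, qbinom(1 - 1e-6, n_pos, 20^-4))
  })
})

test_that("zipper scanning distinguishes complete and partial frames", {
  full <- scanZipper("LAAAAAALAAALAAAAAAL")
  expect_true(full$complete)
  expect_equal(full$span, c(1L, 19L))
  part <- scanZipper("LAAAAAALAAAKAAAAAAL")
  expect_false(part$complete)
  expect_equal(part$n_anchors, 3L)
  # valine/isoleucine anchors are hydrophobic and count as complete
  expect_true(scanZipper("VAAAAAAIAAALAAAAAAV")$complete)
  # strict-leucine mode rejects them (only 1 L anchor: no reportable frame)
  expect_null(scanZipper("VAAAAAAIAAALAAAAAAV",
                         grammar = motifGrammar(zipper_alphabet = "L")))
  expect_null(scanZipper("AAAAAAAAAAAAAAAAAAA"))
})

test_that("zipper scanning prefers the first complete frame; oracle agrees", {
  withr::with_seed(202, {
    for (i in 1:50) {
      s <- paste(sample(c("L", "V", "I", "A", "G", "S"), 80, replace = TRUE),
                 collapse = "")
      z <- scanZipper(s)
      o <- oracleZipperStart(s)
      if (!is.null(z) && z$complete) {
        expect_equal(z$span[1], o)
      } else {
        expect_true(is.na(o))
      }
    }
  })
})

test_that("GAS block anchors are located with strict/relaxed semantics", {
  s <- "AAAFAAVHAAADPVYGAAA"
  g <- scanGasBlock(s)
  expect_equal(g$span, c(4L, 16L))
  expect_true(g$anchor2_strict)
  # P missing: anchor2 fails even in relaxed mode
  expect_null(scanGasBlock("AAAFAAVHAAADAVYGAAA"))
  # D replaced: strict mode rejects, relaxed accepts (P and G conserved)
  s2 <- "AAAFAAVHAAAKPVYGAAA"
  expect_null(scanGasBlock(s2))
  g2 <- scanGasBlock(s2, grammar = motifGrammar(gas_strict = FALSE))
  expect_false(g2$anchor2_strict)
  expect_equal(g2$span, c(4L, 16L))
})

test_that("classification partitions sequences into exactly one class", {
  p1 <- paste0("CAACAAAAAACAAAC", "AAAA", "FAAVHAAADPVYG", "AAAA",
               "LAAAAAALAAALAAAAAAL")
  a1 <- classifyProtein(p1)
  expect_identical(classCall(a1), "I")
  sp <- blockSpans(a1)
  expect_true(sp$c_block[1] < sp$gas[1] && sp$gas[2] < sp$zipper[1])
  # broken anchor -> class II
  p2 <- sub("LAAAAAALAAALAAAAAAL", "LAAAAAALAAAKAAAAAAL", p1, fixed = TRUE)
  expect_identical(classCall(classifyProtein(p2)), "II")
  # no C-block -> none
  expect_identical(classCall(classifyProtein("MAAAAAAAAAAAAAA")), "none")
  # scanner soundness: reported spans re-match their pattern in isolation
  cb <- substring(p1, sp$c_block[1], sp$c_block[2])
  expect_equal(nrow(scanCBlock(cb)), 1L)
  zp <- substring(p1, sp$zipper[1], sp$zipper[2])
  expect_true(scanZipper(zp)$complete)
})

test_that("synthetic proteome closed loop: zero confusion at zero mutation", {
  sim <- generateProteome(simConfig(seed = 21, n_class1 = 50, n_class2 = 30,
                                    n_decoys = 60))
  ann <- annotateProteome(sim$proteins)
  expect_identical(ann$class, sim$truth$class)
})

test_that("classification degrades monotonically with anchor mutations", {
  # mutating zipper anchors of Class I proteins flips calls away from I
  sim <- generateProteome(simConfig(seed = 22, n_class1 = 40, n_class2 = 0,
                                    n_decoys = 0))
  seqs <- as.character(sim$proteins)
  breakAnchors <- function(s, k) {
    a <- classifyProtein(s)
    z <- blockSpans(a)$zipper
    off <- c(0L, 7L, 11L, 18L)
    ch <- strsplit(s, "")[[1]]
    ch[z[1] + off[seq_len(k)]] <- "G"
    paste(ch, collapse = "")
  }
  acc <- vapply(c(0L, 1L, 3L), function(k) {
    called <- vapply(seqs, function(s) {
      classCall(classifyProtein(if (k > 0) breakAnchors(s, k) else s))
    }, character(1))
    mean(called == "I")
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) <= 0))
  expect_equal(acc[3], 0)
})

test_that("conserved blocks match construction and the all-windows oracle", {
  withr::with_seed(33, {
    aln <- replicate(4, paste(sample(c("A", "C", "D", "E"), 40, TRUE),
                              collapse = ""))
    core <- paste(rep("W", 12), collapse = "")
    aln <- paste0(substr(aln, 1, 14), core, substr(aln, 27, 40))
    found <- findConservedBlocks(aln, min_len = 10, min_conservation = 0.9)
    expect_equal(nrow(found), 1L)
    expect_equal(c(found$start, found$end), c(15L, 26L))
    expect_equal(found$length, 12L)
  })
  # boundary: 2/4 agreement per column qualifies at 0.5 (inclusive)
  half <- c("AAAAAAAAAA", "AAAAAAAAAA", "CDEFGHIKLM", "MLKIHGFEDC")
  expect_equal(nrow(findConservedBlocks(half, 10, 0.5)), 1L)
  expect_error(findConservedBlocks(c("AAA", "AAAA")), "ragged")
  # oracle equivalence on random gapped alignments
  withr::with_seed(34, {
    for (rep in 1:20) {
      rows <- replicate(6, paste(sample(c("A", "C", "D", "-"), 60, TRUE,
                                        prob = c(.4, .3, .2, .1)),
                                 collapse = ""))
      got <- findConservedBlocks(rows, min_len = 5, min_conservation = 0.5)
      want <- oracleConservedBlocks(rows, 5L, 0.5)
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        expect_equal(got$start, vapply(want, `[[`, integer(1), "start"))
        expect_equal(got$end, vapply(want, `[[`, integer(1), "end"))
      }
    }
  })
})
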