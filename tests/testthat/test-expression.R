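.toySE <- function(vals) {
  meta <- data.frame(tissue = rep(c("leaf", "root"),
                                  length.out = ncol(vals)),
                     condition = "ctrl", platform = "synthetic",
                     row.names = colnames(vals))
  expressionMatrix(vals, meta)
}

test_that("expression container validates its inputs", {
  m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  storage.mode(m) <- "double"
  se <- .toySE(m)
  expect_s4_class(se, "SummarizedExperiment")
  bad <- m; bad[1] <- NA
  expect_error(.toySE(bad), "finite")
  dup <- m; rownames(dup) <- c("g1", "g1")
  expect_error(.toySE(dup), "unique")
  expect_error(expressionMatrix(m, data.frame(tissue = "x",
                                              row.names = "s1")),
               "metadata")
})

test_that("tissue assignment uses the inclusive log2(256) = 8 threshold", {
  vals <- rbind(at8 = c(8, 8, 5, 5), below = c(7.99, 7.99, 7.99, 7.99),
                high = c(9, 9, 9, 9))
  colnames(vals) <- paste0("s", 1:4)
  meta <- data.frame(tissue = c("leaf", "leaf", "root", "root"),
                     condition = "ctrl", platform = "p",
                     row.names = colnames(vals))
  se <- expressionMatrix(vals, meta)
  calls <- assignTissueOntology(se)
  expect_identical(calls$tissue[calls$gene == "at8"], "leaf")
  expect_false("below" %in% calls$gene)
  expect_setequal(calls$tissue[calls$gene == "high"], c("leaf", "root"))
  # every assigned label exists in the sample metadata
  expect_true(all(calls$tissue %in% meta$tissue))
  # max mode assigns on a single high replicate
  vals2 <- rbind(spiky = c(9, 5, 5, 5))
  colnames(vals2) <- paste0("s", 1:4)
  se2 <- expressionMatrix(vals2, meta)
  expect_equal(nrow(assignTissueOntology(se2)), 0L)
  expect_equal(assignTissueOntology(se2, stat = "max")$tissue, "leaf")
})

test_that("centering is exact and idempotent", {
  vals <- rbind(g1 = c(6, 10), g2 = c(3, 3))
  colnames(vals) <- c("s1", "s2")
  out <- centerRelative(vals)
  expect_equal(out["g1", ], c(s1 = -2, s2 = 2))
  expect_equal(out["g2", ], c(s1 = 0, s2 = 0))
  expect_equal(centerRelative(out), out)
})

test_that("clustering follows the strict distance cut", {
  vals <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2 + 1,
                anti = c(4, 3, 2, 1), lone = c(2, 9, 1, 7))
  colnames(vals) <- paste0("s", 1:4)
  cl <- coexpressionClusters(vals, 0.2)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$members, c("a", "b"))  # d = 0 (scale invariance)
  expect_equal(cl[[1]]$max_internal_distance, 0)
  # anti-correlated rows are at distance 2: never clustered
  cl2 <- coexpressionClusters(vals[c("a", "anti"), ], 0.2)
  expect_length(cl2, 0L)
  # zero-variance rows excluded with a warning
  withvar0 <- rbind(vals, flat = c(5, 5, 5, 5))
  expect_warning(coexpressionClusters(withvar0, 0.2), "zero-variance")
  expect_error(coexpressionClusters(vals[, 1:2]), "3 samples")
})

test_that("clusters at a smaller threshold refine those at a larger one", {
  ex <- generateExpression(simConfig(seed = 81, n_modules = 3L,
                                     module_pcc = 0.9))
  vals <- SummarizedExperiment::assay(ex$se, "log2")
  thresholds <- c(0.1, 0.2, 0.4)
  clusters <- lapply(thresholds, function(t) {
    suppressWarnings(coexpressionClusters(vals, t))
  })
  for (i in 1:2) {
    fine <- clusters[[i]]
    coarse <- clusters[[i + 1]]
    for (cl in fine) {
      containing <- Filter(function(cc) all(cl$members %in% cc$members),
                           coarse)
      expect_length(containing, 1L)
    }
  }
})

test_that("planted modules are recovered at 0.95 but not at 0.5", {
  hits95 <- 0L
  for (seed in 1:10) {
    ex <- generateExpression(simConfig(seed = seed, module_pcc = 0.95))
    cl <- coexpressionClusters(ex$se, 0.2)
    sets <- lapply(cl, `[[`, "members")
    ok <- all(vapply(ex$truth$modules, function(mod) {
      any(vapply(sets, identical, logical(1), y = sort(mod)))
    }, logical(1)))
    hits95 <- hits95 + ok
  }
  expect_gte(hits95, 9L)
  for (seed in 1:5) {
    ex <- generateExpression(simConfig(seed = seed, module_pcc = 0.5))
    cl <- coexpressionClusters(ex$se, 0.2)
    sets <- lapply(cl, `[[`, "members")
    recovered <- vapply(ex$truth$modules, function(mod) {
      any(vapply(sets, identical, logical(1), y = sort(mod)))
    }, logical(1))
    expect_false(any(recovered))
  }
})

test_that("neighbor lists agree with clustering and rank by distance", {
  vals <- rbind(q = c(1, 2, 3, 4, 5), same = c(1, 2, 3, 4, 5),
                close = c(1.1, 1.9, 3.2, 3.9, 5.1), far = c(5, 1, 4, 2, 3))
  colnames(vals) <- paste0("s", 1:5)
  nb <- neighborsOf(vals, "q", 0.2)
  expect_identical(nb$partner[1], "same")
  expect_equal(nb$distance[1], 0)
  expect_false("far" %in% nb$partner)
  expect_true(all(diff(nb$distance) >= 0))
  expect_error(neighborsOf(vals, "nope"), "unknown gene")
  # consistency with clusters on synthetic data
  ex <- generateExpression(simConfig(seed = 82))
  cl <- coexpressionClusters(ex$se, 0.2)
  for (clu in cl) {
    g <- clu$members[1]
    nb <- neighborsOf(ex$se, g, 0.2)
    # cluster mates are mutual neighbors under the same threshold for pairs,
    # modulo average-linkage chaining; direct-distance mates must be there
    direct <- setdiff(clu$members, g)
    dm <- 1 - cor(t(SummarizedExperiment::assay(ex$se, "log2")))
    direct <- direct[dm[g, direct] < 0.2]
    expect_true(all(direct %in% nb$partner))
  }
})

test_that("condition contrasts are antisymmetric descriptive differences", {
  vals <- rbind(g1 = c(5, 5, 6, 6), g2 = c(7, 7, 7, 7))
  colnames(vals) <- paste0("s", 1:4)
  a <- c("s1", "s2"); b <- c("s3", "s4")
  ct <- conditionContrast(vals, a, b)
  expect_equal(ct$log2_diff, c(-1, 0))
  expect_equal(conditionContrast(vals, b, a)$log2_diff, c(1, 0))
  expect_equal(conditionContrast(vals, a, a)$log2_diff, c(0, 0))
  expect_error(conditionContrast(vals, "s9", b), "unknown sample")
})

test_that("clustering is invariant to affine rescaling of a gene row", {
  ex <- generateExpression(simConfig(seed = 83, n_modules = 1L))
  vals <- SummarizedExperiment::assay(ex$se, "log2")
  g <- ex$truth$modules[[1]][1]
  scaled <- vals
  scaled[g, ] <- 3 * scaled[g, ] + 7
  cl1 <- suppressWarnings(coexpressionClusters(vals, 0.2))
  cl2 <- suppressWarnings(coexpressionClusters(scaled, 0.2))
  expect_identical(lapply(cl1, `[[`, "members"),
                   lapply(cl2, `[[`, "members"))
})
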