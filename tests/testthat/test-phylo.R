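test_that("column filtering matches the per-column coverage count", {
  msa <- c(a = "AAC-A", b = "AA--A", c = "AACCA", d = "AACCA",
           e = "AACCA", f = "AACCA", g = "AACCA", h = "AACCA",
           i = "AACCA", j = "AACCA")
  # column 4 has coverage 0.9 -> removed at 0.95; column 3 has 0.9 too
  out <- filterColumns(msa, 0.95)
  expect_equal(unique(Biostrings::width(out)), 3L)
  gapfree <- c(a = "AAAA", b = "CCCC", c = "GGGG")
  expect_equal(as.character(filterColumns(gapfree, 0.95)),
               unname(gapfree), ignore_attr = TRUE)
  expect_error(filterColumns(c(a = "--", b = "--", c = "AA"), 0.95), "all columns")
  # oracle equivalence on random gapped alignments
  withr::with_seed(55, {
    for (rep in 1:10) {
      m <- matrix(sample(c("A", "C", "-"), 8 * 30, TRUE, prob = c(.45, .45, .1)),
                  nrow = 8)
      rownames(m) <- paste0("t", 1:8)
      keep <- colSums(m != "-") / 8 >= 0.9
      if (!any(keep)) next
      expect_identical(filterColumns(m, 0.9), m[, keep, drop = FALSE])
    }
  })
})

test_that("protein distances follow p and Poisson definitions", {
  msa <- c(a = "AAAA", b = "AAAC", c = "AACC")
  d <- proteinDistance(msa, model = "p")
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0.5)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(unname(d)))
  dp <- proteinDistance(msa, model = "poisson")
  expect_equal(dp["a", "b"], -log(1 - 0.25))
  # identical sequences at distance 0; pairwise deletion of gap sites
  msa2 <- c(a = "AA-A", b = "AACA", c = "AAAA")
  d2 <- proteinDistance(msa2, model = "p")
  expect_equal(d2["a", "b"], 0)
  expect_error(proteinDistance(c(a = "A---", b = "-A--", c = "AA--"), "p"),
               "no comparable sites")
  expect_error(proteinDistance(c(a = "AA", b = "AC"), "p"), "at least 3")
})

test_that("neighbor joining is exact on additive matrices", {
  # 4 taxa from tree ((A:1,B:2):1,(C:3,D:4))
  lab <- c("A", "B", "C", "D")
  d4 <- matrix(0, 4, 4, dimnames = list(lab, lab))
  d4["A", "B"] <- 3; d4["A", "C"] <- 5; d4["A", "D"] <- 6
  d4["B", "C"] <- 6; d4["B", "D"] <- 7; d4["C", "D"] <- 7
  d4 <- d4 + t(d4)
  tr <- njTree(d4)
  # additive input: path lengths on the tree reproduce the matrix exactly
  expect_equal(ape::cophenetic.phylo(tr)[lab, lab], d4)
  # the AB|CD split is present
  splits <- ape::prop.part(tr)
  labs <- attr(splits, "labels")
  sets <- lapply(splits, function(s) sort(labs[s]))
  expect_true(list(c("A", "B")) %in% sets || list(c("C", "D")) %in% sets)

  # 5 taxa: ((A:1,B:2):1,((C:3,D:4):2,E:5)) style additive matrix
  lab5 <- c("A", "B", "C", "D", "E")
  d5 <- matrix(0, 5, 5, dimnames = list(lab5, lab5))
  d5["A", "B"] <- 3
  d5["A", "C"] <- 7; d5["A", "D"] <- 8; d5["A", "E"] <- 7
  d5["B", "C"] <- 8; d5["B", "D"] <- 9; d5["B", "E"] <- 8
  d5["C", "D"] <- 7; d5["C", "E"] <- 10; d5["D", "E"] <- 11
  d5 <- d5 + t(d5)
  tr5 <- njTree(d5)
  expect_equal(ape::cophenetic.phylo(tr5)[lab5, lab5], d5)
  # agrees with the independent NJ implementation in ape
  ref <- ape::nj(as.dist(d5))
  expect_equal(ape::dist.topo(ape::unroot(tr5), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("three-taxon trees use the three-point formula", {
  lab <- c("x", "y", "z")
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, dimnames = list(lab, lab))
  tr <- njTree(d)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("x", "y", "z")]), c(1, 1, 2))
})

test_that("NJ topology is invariant to taxon order; asymmetry errors", {
  withr::with_seed(77, {
    m <- matrix(sample(c("A", "C", "D", "E", "G"), 6 * 50, TRUE), nrow = 6)
    rownames(m) <- paste0("t", 1:6)
    d <- proteinDistance(m, "p")
    tr1 <- njTree(d)
    perm <- sample(6)
    tr2 <- njTree(d[perm, perm])
    expect_equal(ape::dist.topo(ape::unroot(tr1), ape::unroot(tr2)), 0,
                 ignore_attr = TRUE)
  })
  bad <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(njTree(bad), "symmetric")
})

test_that("bootstrap supports a fully concordant split at 100", {
  msa <- c(A = "AAAAAKKKKK", B = "AAAAAKKKKK",
           C = "DDDDDKKKKK", D = "DDDDDKKKKK")
  st <- bootstrapTree(msa, n_reps = 100, seed = 5, collapse_below = 30,
                      model = "p")
  s <- supportValues(st)
  expect_equal(s[!is.na(s)], 100)
  expect_true(all(supportValues(st) >= 0, na.rm = TRUE))
  expect_true(all(supportValues(st) <= 100, na.rm = TRUE))
  # reproducibility under a fixed seed
  st2 <- bootstrapTree(msa, n_reps = 100, seed = 5, collapse_below = 30,
                       model = "p")
  expect_identical(supportValues(st), supportValues(st2))
  expect_identical(ape::write.tree(treeOf(st)), ape::write.tree(treeOf(st2)))
  expect_error(bootstrapTree(msa, n_reps = 0, seed = 1), "n_reps")
})

test_that("collapse contracts weak edges but collapse_below = 0 keeps all", {
  withr::with_seed(88, {
    m <- matrix(sample(c("A", "C", "D", "E", "G", "H"), 8 * 30, TRUE), nrow = 8)
    rownames(m) <- paste0("t", 1:8)
    st0 <- bootstrapTree(m, n_reps = 60, seed = 3, collapse_below = 0,
                         model = "p")
    expect_identical(ape::write.tree(collapsedTree(st0)),
                     ape::write.tree(treeOf(st0)))
    stc <- bootstrapTree(m, n_reps = 60, seed = 3, collapse_below = 101,
                         model = "p")
    # everything below 101 collapses: a star tree remains
    expect_equal(collapsedTree(stc)$Nnode, 1L)
  })
})

test_that("subclass assignment follows the bootstrap threshold rule", {
  ref <- c(refd = "d", refa = "a", refc = "c")
  high <- ape::read.tree(text = "((q:1,refd:1)85:1,(refa:1,refc:1)99:1,o:1);")
  a <- assignSubclasses(high, ref)
  qa <- a[a$gene == "q", ]
  expect_identical(qa$status, "assigned")
  expect_identical(qa$subclass, "d")
  expect_equal(qa$support, 85)
  expect_identical(qa$evidence, "phylogeny")

  low <- ape::read.tree(text = "((q:1,refd:1)54:1,(refa:1,refc:1)99:1,o:1);")
  ql <- assignSubclasses(low, ref)
  ql <- ql[ql$gene == "q", ]
  expect_identical(ql$status, "motif_needed")
  expect_true(is.na(ql$subclass))
  expect_equal(ql$support, 54)

  mixed <- ape::read.tree(text = "((q:1,(refc:1,refd:1)90:1)95:1,refa:1,o:1);")
  qm <- assignSubclasses(mixed, ref)
  qm <- qm[qm$gene == "q", ]
  expect_identical(qm$status, "unassigned")
  expect_true(is.na(qm$subclass))

  expect_error(assignSubclasses(high, c(ref, zz = "z")), "absent from tree")
})

test_that("raising min_support never gains assignments", {
  ref <- c(refd = "d", refa = "a", refc = "c")
  tr <- ape::read.tree(
    text = "((q1:1,refd:1)72:1,((q2:1,refa:1)55:1,refc:1)90:1,o:1);")
  counts <- vapply(c(40, 70, 90), function(ms) {
    sum(assignSubclasses(tr, ref, min_support = ms)$status == "assigned")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
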