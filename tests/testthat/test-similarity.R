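test_that("GIP kernel matches the closed form and brute force", {
  expect_equal(gipSimilarity(diag(2))[1, 2], exp(-2), tolerance = 1e-12)
  A <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0))
  expect_equal(gipSimilarity(A)[1, 2], 1)  # identical profiles
  for (s in 1:3) {
    A <- randomBinaryMatrix(10, 8, 0.4, seed = s)
    K <- gipSimilarity(A, "rows")
    expect_equal(K, bruteForceGip(A), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(K, t(K))
    expect_equal(unname(diag(K)), rep(1, 10))
    expect_true(all(K > 0 & K <= 1))
  }
  expect_error(gipSimilarity(matrix(0, 3, 3)), "bandwidth")
})

test_that("Wang semantic similarity matches hand values and recursion", {
  dag <- data.frame(child = c("a", "b"), parent = c("root", "a"))
  M <- diseaseSemanticSimilarity(dag, decay = 0.5)
  expect_equal(M["a", "b"], (0.5 + 1 + 0.25 + 0.5) / (1.75 + 1.5),
               tolerance = 1e-12)
  expect_equal(unname(diag(M)), rep(1, 3))
  # two disconnected roots share no ancestors
  dag2 <- data.frame(child = c("a", "b"), parent = c("r1", "r2"))
  expect_equal(diseaseSemanticSimilarity(dag2)["r1", "r2"], 0)
  # random small DAGs against the naive recursive definition
  for (s in 1:5) {
    ed <- randomDag(sample(5:12, 1), seed = s)
    expect_equal(diseaseSemanticSimilarity(ed, decay = 0.5),
                 bruteForceWang(ed, 0.5), tolerance = 1e-10)
  }
  cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(diseaseSemanticSimilarity(cyc), "cycle")
})

test_that("functional similarity is the best-match average over disease sets", {
  sem <- diag(1, 2)
  sem[1, 2] <- sem[2, 1] <- 0.6
  A <- rbind(c(1, 0), c(0, 1))
  M <- mirnaFunctionalSimilarity(sem, A)
  expect_equal(M[1, 2], 0.6, tolerance = 1e-12)
  # identical disease sets give 1; empty sets stay at the unit diagonal
  A2 <- rbind(c(1, 1), c(1, 1), c(0, 0))
  M2 <- mirnaFunctionalSimilarity(sem, A2)
  expect_equal(M2[1, 2], 1)
  expect_equal(unname(M2[3, ]), c(0, 0, 1))
  expect_error(mirnaFunctionalSimilarity(sem, matrix(0, 2, 3)), "match")
})

test_that("sequence similarity reproduces hand alignments", {
  expect_equal(mirnaSequenceSimilarity(c(a = "ACGU", b = "ACGU"))[1, 2], 1)
  expect_equal(mirnaSequenceSimilarity(c(a = "AAAA", b = "CCCC"))[1, 2], 0)
  expect_equal(mirnaSequenceSimilarity(c(a = "AACC", b = "AAGG"))[1, 2], 0.5)
  expect_error(mirnaSequenceSimilarity(c(a = "ACGX")), "invalid character")
})

test_that("target similarity is the Jaccard index with empty-set conventions", {
  gs <- list(d1 = c("g1", "g2"), d2 = c("g2", "g3"), d3 = character(0))
  M <- diseaseTargetSimilarity(gs)
  expect_equal(M["d1", "d2"], 1 / 3, tolerance = 1e-12)
  expect_equal(M["d1", "d3"], 0)
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_equal(diseaseTargetSimilarity(list(a = "g", b = "g"))[1, 2], 1)
})

test_that("disease gene sets collect associated miRNAs' targets", {
  A <- rbind(c(1, 0), c(1, 1))
  sets <- diseaseGeneSets(A, list(c("g1"), c("g2", "g3")))
  expect_identical(sets[[1]], c("g1", "g2", "g3"))
  expect_identical(sets[[2]], c("g2", "g3"))
})

test_that("all six synthetic views satisfy the similarity invariants", {
  sim <- generateSynthetic(syntheticSpec(km = 25, kd = 15, rank = 3, seed = 2))
  for (vs in list(sim$mirnaViews, sim$diseaseViews)) {
    expect_true(validObject(vs))
    for (nm in viewNames(vs)) {
      V <- getView(vs, nm)
      expect_lt(max(abs(V - t(V))), 1e-10)
      expect_true(all(V >= 0 & V <= 1))
      expect_equal(unname(diag(V)), rep(1, nrow(V)))
    }
  }
})
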