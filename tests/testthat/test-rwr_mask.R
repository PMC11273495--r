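test_that("start-node sampling honours boundary rates and concentrates", {
  expect_identical(sampleStartNodes(10, p = 0), integer(0))
  expect_identical(sampleStartNodes(10, p = 1), 1:10)
  expect_error(sampleStartNodes(10, p = 1.5), "p must")
  rates <- vapply(1:100, function(s)
    length(sampleStartNodes(10000, p = 0.3, seed = s)) / 10000, 0)
  expect_gt(mean(rates), 0.27)
  expect_lt(mean(rates), 0.33)
})

test_that("transition matrix matches the restart closed form", {
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(rwrTransitionMatrix(A, c = 0.6),
               matrix(c(0.6, 0.4, 0.4, 0.6), 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(rwrTransitionMatrix(A, c = 1), diag(2),
               ignore_attr = TRUE)
  expect_equal(rwrTransitionMatrix(A, c = 0), A[2:1, 2:1],
               ignore_attr = TRUE)
  expect_error(rwrTransitionMatrix(-A, c = 0.5), "nonnegative")
})

test_that("transition rows are stochastic with isolated-node self-loops", {
  for (s in 1:5) {
    A <- randomBinaryMatrix(8, 8, 0.3, seed = s)
    A <- A * upper.tri(A); A <- A + t(A)
    A[2, ] <- 0; A[, 2] <- 0  # force an isolated node
    P <- rwrTransitionMatrix(A, c = 0.6)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_equal(P[2, 2], 1)
  }
})

test_that("path extraction follows the restart walker semantics", {
  A <- matrix(c(0, 1, 1, 0), 2)
  P <- rwrTransitionMatrix(A, c = 0)
  expect_identical(extractPath(P, 1, k = 0), 1L)
  expect_identical(extractPath(P, 1, k = 3, seed = 1), c(1L, 2L, 1L, 2L))
  P1 <- rwrTransitionMatrix(randomSimilarity(6, seed = 2), c = 1)
  expect_identical(extractPath(P1, 4, k = 5, seed = 1), rep(4L, 6))
  expect_identical(extractPath(P1, 4, k = 5, seed = 1),
                   extractPath(P1, 4, k = 5, seed = 1))
})

test_that("mask vectors record path membership", {
  expect_identical(pathMaskVector(c(1, 2), 3), c(1, 1, 0))
  expect_identical(pathMaskVector(c(1, 1, 1), 2), c(1, 0))
  expect_identical(pathMaskVector(3, 3), c(0, 0, 1))
  expect_error(pathMaskVector(5, 3), "path entries")
})

test_that("mask application covers the K3 example in both modes", {
  K3 <- matrix(1, 3, 3) - diag(3)
  m <- list(c(1, 1, 0))
  lit <- applyAssociationMask(K3, m, mode = "literal")
  comp <- applyAssociationMask(K3, m, mode = "complement")
  expect_equal(maskedAdjacency(lit),
               matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3))
  expect_equal(maskedAdjacency(comp),
               matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3))
  # coverage duality: the two modes partition A
  expect_equal(maskedAdjacency(lit) + maskedAdjacency(comp), K3)
  # masked entries recorded for the complement mode
  expect_equal(nrow(maskedEntries(comp)), 2L)
})

test_that("empty and full coverages behave as pass-through and blackout", {
  A <- randomSimilarity(5, seed = 1)
  expect_equal(maskedAdjacency(applyAssociationMask(A, list())), A)
  out <- applyAssociationMask(A, list(rep(1, 5)), mode = "complement")
  expect_true(all(maskedAdjacency(out) == 0))
  mg <- maskSimilarityView(A, p = 0, seed = 3)
  expect_equal(maskedAdjacency(mg), A)
  expect_equal(nrow(maskedEntries(mg)), 0L)
})

test_that("symmetric inputs stay symmetric and masking grows with p", {
  A <- randomSimilarity(12, seed = 5)
  nMasked <- vapply(c(0.1, 0.5, 0.9), function(p) {
    mean(vapply(1:10, function(s) {
      mg <- maskSimilarityView(A, p = p, seed = s)
      expect_lt(max(abs(maskedAdjacency(mg) - t(maskedAdjacency(mg)))), 1e-12)
      nrow(maskedEntries(mg))
    }, 0))
  }, 0)
  expect_true(all(diff(nMasked) > 0))
})

test_that("RWR stationary distribution keeps restart mass on the start node", {
  for (s in 1:4) {
    A <- randomBinaryMatrix(8, 8, 0.5, seed = s)
    A <- (A + t(A)) > 0; diag(A) <- 0; A <- A * 1
    deg <- rowSums(A)
    A[deg == 0, 1] <- A[1, deg == 0] <- 1  # connect isolates for the check
    cR <- 0.6
    P <- rwrTransitionMatrix(A, c = cR)
    W <- (P - cR * diag(8)) / (1 - cR)  # the walk's neighbour kernel
    v <- 3L
    e <- numeric(8); e[v] <- 1
    x <- e
    for (it in 1:200) x <- (1 - cR) * crossprod(W, x)[, 1] + cR * e
    expect_gte(x[v] + 1e-9, cR)
  }
})
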