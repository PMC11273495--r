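test_that("cosine weights match hand values and conventions", {
  expect_equal(cosineWeights(matrix(c(1, 2), 1), matrix(c(2, 1), 1))[1, 1],
               0.8, tolerance = 1e-12)
  v <- matrix(c(3, 4), 1)
  expect_equal(cosineWeights(v, v)[1, 1], 1)
  expect_equal(cosineWeights(matrix(c(1, 0), 1), matrix(c(0, 1), 1))[1, 1], 0)
  expect_equal(cosineWeights(matrix(0, 1, 2), v)[1, 1], 0)  # zero-norm row
  # scale invariance
  set.seed(31)
  X <- matrix(rnorm(12), 3, 4); Q <- matrix(rnorm(8), 2, 4)
  expect_equal(cosineWeights(3.7 * X, 0.2 * Q), cosineWeights(X, Q),
               tolerance = 1e-12)
  expect_error(cosineWeights(X, matrix(0, 2, 3)), "dimensions")
})

test_that("hypergraph assembly wires supernodes, positives and the guard", {
  set.seed(32)
  Xm <- matrix(rnorm(12), 3, 4)
  Xd <- matrix(rnorm(8), 2, 4)
  Q <- matrix(rnorm(4), 1, 4)
  kp <- cbind(c(1, 3), c(2, 1))
  b <- assembleHypergraph(Xm, Xd, Q, knownPairs = kp)
  A <- b@Ahyper
  expect_equal(A, t(A))
  expect_equal(A[1, 3 + 2], 1)  # known associations carry weight 1
  expect_equal(A[3, 3 + 1], 1)
  expect_equal(sum(A[1:3, 4:5]), 2)
  expect_equal(A[1:3, 6], pmax(b@Cmq[, 1], 0))  # ReLU-clipped cosines
  expect_true(all(A >= 0))
  # empty-known-pairs case: bipartite block all zero
  b0 <- assembleHypergraph(Xm, Xd, Q)
  expect_true(all(b0@Ahyper[1:3, 4:5] == 0))
  # leakage guard trips on a held-out pair among the edges
  expect_error(
    assembleHypergraph(Xm, Xd, Q, knownPairs = kp,
                       forbiddenPairs = cbind(3, 1)),
    "leakage")
})

test_that("a single all-positive supernode couples to every node", {
  Xm <- matrix(abs(rnorm(8)) + 0.1, 2, 4)
  Xd <- matrix(abs(rnorm(12)) + 0.1, 3, 4)
  Q <- matrix(abs(rnorm(4)) + 0.1, 1, 4)
  A <- assembleHypergraph(Xm, Xd, Q)@Ahyper
  expect_true(all(A[6, 1:5] > 0))
})

test_that("shortest paths match the chain example, the cap and Floyd-Warshall", {
  chain <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  expect_equal(shortestPathMatrix(chain),
               matrix(c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 0L), 3))
  disc <- diag(0, 2)
  expect_equal(shortestPathMatrix(disc, maxSp = 8)[1, 2], 8L)
  for (s in 1:10) {
    A <- randomBinaryMatrix(8, 8, 0.25, seed = 100 + s)
    A <- ((A + t(A)) > 0) * 1; diag(A) <- 0
    expect_equal(shortestPathMatrix(A, maxSp = 8),
                 floydWarshall(A, 8), ignore_attr = TRUE)
  }
})

test_that("SP-biased attention hits its analytic limits and hand values", {
  set.seed(33)
  n <- 4; E <- 4
  H <- matrix(rnorm(n * E), n, E)
  D <- floydWarshall((randomBinaryMatrix(n, n, 0.5, seed = 9) +
                       t(randomBinaryMatrix(n, n, 0.5, seed = 9)) > 0) * 1, 8)
  storage.mode(D) <- "integer"; diag(D) <- 0L
  Z <- matrix(0, E, E)
  Wv <- diag(E)
  # zero query/key and zero bias: uniform attention = column means of V
  out <- spBiasedAttention(H, Z, Z, Wv, diag(E), D, heads = 1L,
                           distanceBias = rep(0, 9))
  expect_equal(out$output,
               matrix(colMeans(H), n, E, byrow = TRUE), tolerance = 1e-12)
  expect_equal(rowSums(out$attention[[1]]), rep(1, n), tolerance = 1e-12)
  # near -Inf off-diagonal bias collapses attention onto self: output = V
  selfD <- matrix(1L, n, n); diag(selfD) <- 0L
  out2 <- spBiasedAttention(H, Z, Z, Wv, diag(E), selfD, heads = 1L,
                            distanceBias = c(0, -1e6))
  expect_equal(out2$output, H, tolerance = 1e-9)
  # raw-distance mode against a by-hand softmax
  Wq <- matrix(0.1, E, E); Wk <- matrix(0.2, E, E)
  out3 <- spBiasedAttention(H, Wq, Wk, Wv, diag(E), D, heads = 1L,
                            biasMode = "raw")
  logits <- (H %*% Wq) %*% t(H %*% Wk) / sqrt(E) + D
  probs <- exp(logits) / rowSums(exp(logits))
  expect_equal(out3$output, probs %*% H, tolerance = 1e-10)
  expect_error(spBiasedAttention(H * NaN, Z, Z, Wv, diag(E), D), "NaN")
})

# Independent straight-line forward pass of one GCN-Transformer layer,
# written from the layer definition with explicit loops.
naiveGctLayer <- function(H, A, D, p, heads, distanceBias) {
  W <- A + diag(nrow(A))
  d <- rowSums(W)
  Ahat <- W / sqrt(d) / rep(sqrt(d), each = nrow(A))
  G <- pmax(Ahat %*% H %*% p$Wg, 0)
  E <- ncol(H); dk <- E / heads
  B <- matrix(distanceBias[D + 1], nrow(D), ncol(D))
  heads_out <- NULL
  for (h in seq_len(heads)) {
    cols <- (h - 1) * dk + seq_len(dk)
    Qh <- G %*% p$Wq[, cols]; Kh <- G %*% p$Wk[, cols]; Vh <- G %*% p$Wv[, cols]
    L <- Qh %*% t(Kh) / sqrt(dk) + B
    P <- exp(L - apply(L, 1, max))
    P <- P / rowSums(P)
    heads_out <- cbind(heads_out, P %*% Vh)
  }
  att <- heads_out %*% p$WO
  ln <- function(X, g, b) {
    mu <- rowMeans(X); va <- rowMeans((X - mu)^2)
    xh <- (X - mu) / sqrt(va + 1e-5)
    sweep(xh * rep(as.numeric(g), each = nrow(X)), 2, as.numeric(b), "+")
  }
  R1 <- ln(G + att, p$ln1g, p$ln1b)
  FF <- pmax(sweep(R1 %*% p$F1, 2, as.numeric(p$b1), "+"), 0) %*% p$F2
  FF <- sweep(FF, 2, as.numeric(p$b2), "+")
  ln(R1 + FF, p$ln2g, p$ln2b)
}

test_that("encoder layers reproduce an independent straight-line forward", {
  set.seed(34)
  n <- 6; E <- 8; heads <- 2
  A <- ((randomBinaryMatrix(n, n, 0.4, seed = 3) +
          t(randomBinaryMatrix(n, n, 0.4, seed = 3))) > 0) * 1
  diag(A) <- 0
  H <- matrix(rnorm(n * E), n, E)
  D <- shortestPathMatrix(A, maxSp = 8)
  bias <- -0.3 * (0:8)
  p1 <- initGctLayerParams(E, ffnHidden = 12, seed = 5)
  p2 <- initGctLayerParams(E, ffnHidden = 12, seed = 6)
  got <- gctEncoderLayer(H, A, D, p1, heads = heads, distanceBias = bias)
  ref1 <- naiveGctLayer(H, A, D, p1, heads, bias)
  expect_equal(got, ref1, tolerance = 1e-10, ignore_attr = TRUE)
  # two stacked layers
  got2 <- gctEncoderLayer(got, A, D, p2, heads = heads, distanceBias = bias)
  expect_equal(got2, naiveGctLayer(ref1, A, D, p2, heads, bias),
               tolerance = 1e-9, ignore_attr = TRUE)
  # LayerNorm contract: each output row standardised before gain/offset
  expect_equal(unname(rowMeans(got)), rep(0, n), tolerance = 1e-6)
  expect_equal(unname(apply(got, 1, var)) * (E - 1) / E, rep(1, n),
               tolerance = 1e-3)
  # per-head attention rows sum to one
  for (Pm in attr(got, "attention"))
    expect_equal(rowSums(Pm), rep(1, n), tolerance = 1e-12)
})

test_that("zero attention/FFN projections reduce the layer to LN(GCN)", {
  set.seed(35)
  n <- 5; E <- 4
  A <- matrix(1, n, n) - diag(n)
  H <- matrix(rnorm(n * E), n, E)
  D <- shortestPathMatrix(A)
  p <- initGctLayerParams(E, ffnHidden = 8, seed = 1)
  p$WO <- matrix(0, E, E)
  p$F2 <- matrix(0, 8, E); p$b2 <- matrix(0, 1, E)
  got <- gctEncoderLayer(H, A, D, p, heads = 2)
  G <- pmax(gcnNormalize(A) %*% H %*% p$Wg, 0)
  ln <- function(X) {
    mu <- rowMeans(X); va <- rowMeans((X - mu)^2)
    (X - mu) / sqrt(va + 1e-5)
  }
  expect_equal(got, ln(ln(G)), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("joint encoding splits families, is pure and equivariant", {
  set.seed(36)
  km <- 3; kd <- 2; q <- 1; E <- 8
  Xm <- matrix(rnorm(km * E), km, E)
  Xd <- matrix(rnorm(kd * E), kd, E)
  Q <- matrix(rnorm(q * E), q, E)
  kp <- cbind(c(1, 2), c(1, 2))
  bundle <- assembleHypergraph(Xm, Xd, Q, knownPairs = kp)
  lp <- list(initGctLayerParams(E, 12, seed = 2),
             initGctLayerParams(E, 12, seed = 3))
  z1 <- gctEncode(bundle, lp, heads = 2)
  z2 <- gctEncode(bundle, lp, heads = 2)
  expect_identical(z1, z2)
  expect_equal(dim(z1$Zm), c(km, E))
  expect_equal(dim(z1$Zd), c(kd, E))
  expect_equal(dim(z1$Zq), c(q, E))
  # permuting the miRNA family permutes Zm identically
  perm <- c(3, 1, 2)
  kpPerm <- cbind(match(kp[, 1], perm), kp[, 2])
  bundleP <- assembleHypergraph(Xm[perm, ], Xd, Q, knownPairs = kpPerm)
  zP <- gctEncode(bundleP, lp, heads = 2)
  expect_equal(zP$Zm, z1$Zm[perm, ], tolerance = 1e-10)
  expect_equal(zP$Zd, z1$Zd, tolerance = 1e-10)
})
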