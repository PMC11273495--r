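# The autodiff tape is internal; its hand-derived vector-Jacobian products
# are checked here against central finite differences on composites that
# exercise every op the model uses.

ns <- asNamespace("hgtmda")

fdGrad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("gradients of the encoder-style composite match finite differences", {
  set.seed(11)
  X <- matrix(rnorm(15), 5, 3)
  W0 <- matrix(rnorm(9), 3, 3)
  forward <- function(Wv, tape = NULL) {
    w <- if (is.null(tape)) Wv else ns$adParam(tape, Wv)
    g <- if (is.null(tape)) matrix(1, 1, 3) else ns$adParam(tape, matrix(1, 1, 3))
    H <- ns$adLayerNorm(ns$adRelu(ns$adMM(X, w)), g, matrix(0, 1, 3))
    S <- ns$adSoftmaxRows(ns$adScale(H, 0.7))
    out <- ns$adMean(ns$adMul(S, ns$adSigmoid(H)))
    list(value = ns$adValue(out), node = out, w = w)
  }
  tape <- ns$adTape()
  run <- forward(W0, tape)
  ns$adBackward(run$node)
  num <- fdGrad(function(w) forward(w)$value, W0)
  expect_equal(run$w$grad, num, tolerance = 1e-6)
})

test_that("gradients of gather, bias-embedding, shift and split ops check out", {
  set.seed(12)
  H0 <- matrix(rnorm(24), 6, 4)
  D <- matrix(sample(0:3, 36, TRUE), 6, 6)
  D <- pmax(D, t(D)); diag(D) <- 0
  b0 <- matrix(rnorm(4), 1)
  forward <- function(bv, Hv, tape = NULL) {
    mk <- function(x) if (is.null(tape)) x else ns$adParam(tape, x)
    b <- mk(bv); H <- mk(Hv)
    logits <- ns$adAdd(ns$adScale(ns$adMM(H, ns$adT(H)), 0.5),
                       ns$adGatherBias(b, D))
    att <- ns$adMM(ns$adSoftmaxRows(logits), H)
    parts <- ns$adCbind(list(ns$adRows(att, c(1L, 3L, 3L)),
                             ns$adRows(att, c(2L, 5L, 6L))))
    conv <- ns$adAdd(ns$adShiftCols(parts, 1L), ns$adShiftCols(parts, -1L))
    out <- ns$adSum(ns$adMulCol(conv, mk(matrix(0.3, 3, 1))))
    list(value = as.numeric(ns$adValue(out)), node = out, b = b, H = H)
  }
  tape <- ns$adTape()
  run <- forward(b0, H0, tape)
  ns$adBackward(run$node)
  expect_equal(run$b$grad, fdGrad(function(b) forward(b, H0)$value, b0),
               tolerance = 1e-6)
  expect_equal(run$H$grad, fdGrad(function(H) forward(b0, H)$value, H0),
               tolerance = 1e-6)
})

test_that("scalar division and clipped-log losses differentiate correctly", {
  set.seed(13)
  s0 <- matrix(runif(8, 0.05, 0.95), ncol = 1)
  y <- rbinom(8, 1, 0.5)
  forward <- function(sv, tape = NULL) {
    s <- if (is.null(tape)) sv else ns$adParam(tape, sv)
    out <- ns$.adDceLoss(s, y, alpha = 0.8)
    list(value = as.numeric(ns$adValue(out)), node = out, s = s)
  }
  tape <- ns$adTape()
  run <- forward(s0, tape)
  ns$adBackward(run$node)
  expect_equal(run$s$grad, fdGrad(function(s) forward(s)$value, s0),
               tolerance = 1e-5)
  # numeric fallback agrees with the exported loss
  expect_equal(forward(s0)$value, dceLoss(y, as.numeric(s0), alpha = 0.8),
               tolerance = 1e-12)
})

test_that("ops fall through to plain numerics without a tape", {
  A <- matrix(1:6, 2, 3)
  B <- matrix(1, 3, 2)
  expect_identical(ns$adMM(A, B), A %*% B)
  expect_identical(ns$adRelu(matrix(c(-1, 2), 1)), matrix(c(0, 2), 1))
  expect_equal(ns$adSoftmaxRows(matrix(0, 2, 3)), matrix(1 / 3, 2, 3))
})
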