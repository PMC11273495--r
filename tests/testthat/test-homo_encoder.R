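test_that("GCN layers reproduce hand-unrolled propagation", {
  # identity adjacency without self-loop scaling: Ahat = I when A = 0
  A0 <- matrix(0, 3, 3)
  X0 <- matrix(abs(rnorm(6)), 3, 2)
  expect_equal(gcnViewEncode(A0, X0, list(diag(2))), X0)
  expect_equal(gcnViewEncode(A0, X0, list(matrix(0, 2, 2))),
               matrix(0, 3, 2))
  # 3-node path graph, two layers, against explicit matrix products
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  W1 <- matrix(c(0.2, -0.1, 0.3, 0.4), 2)
  W2 <- matrix(c(0.1, 0.5, -0.2, 0.3), 2)
  Ahat <- gcnNormalize(A)
  ref <- pmax(Ahat %*% pmax(Ahat %*% X0 %*% W1, 0) %*% W2, 0)
  expect_equal(gcnViewEncode(A, X0, list(W1, W2)), ref, tolerance = 1e-12)
  expect_error(gcnViewEncode(A, X0[1:2, ], list(W1)), "rows")
})

test_that("view attention weights live on the simplex and fuse convexly", {
  set.seed(21)
  views <- lapply(1:3, function(i) matrix(rnorm(20), 5, 4))
  out <- attentionFuseViews(views, score = matrix(rnorm(4), 4, 1))
  expect_equal(rowSums(out$weights), rep(1, 5), tolerance = 1e-12)
  expect_true(all(out$weights >= 0))
  # fused lies in the per-node convex hull, coordinate-wise
  lo <- pmin(views[[1]], views[[2]], views[[3]])
  hi <- pmax(views[[1]], views[[2]], views[[3]])
  expect_true(all(out$fused >= lo - 1e-12 & out$fused <= hi + 1e-12))
  # one view passes through with weight 1
  one <- attentionFuseViews(views[1])
  expect_equal(one$fused, views[[1]])
  expect_equal(unname(one$weights[, 1]), rep(1, 5))
  # equal logits average; identical views are fusion-invariant
  same <- attentionFuseViews(views[c(1, 1)], score = matrix(0, 4, 1))
  expect_equal(same$fused, views[[1]])
  mean2 <- attentionFuseViews(views[1:2], score = matrix(0, 4, 1))
  expect_equal(mean2$fused, (views[[1]] + views[[2]]) / 2, tolerance = 1e-12)
  expect_error(attentionFuseViews(list(views[[1]], views[[1]][1:3, ])),
               "share shape")
})

test_that("training gradients reach every view's GCN weights", {
  ns <- asNamespace("hgtmda")
  fx <- miniFixture()
  cfg <- miniConfig(homoDropout = 0, gctDropout = 0, maskP = 0)
  pairs <- head(ns$.labelledPairs(fx$ds), 20)
  mv <- ns$.viewList(fx$sim$mirnaViews)
  dv <- ns$.viewList(fx$sim$diseaseViews)
  set.seed(1)
  P <- ns$.initParams(30L, 20L, cfg)
  inp <- list(AmHat = lapply(mv, gcnNormalize), AdHat = lapply(dv, gcnNormalize),
              trainPos = as.matrix(pairs[pairs$label == 1, c("i", "j")]),
              forbidden = NULL, scorePairs = as.matrix(pairs[, c("i", "j")]))
  # Freeze the hypergraph so finite differences see the same (detached)
  # adjacency the analytic gradient uses.
  warm <- ns$.modelForward(P, inp, cfg, training = FALSE)
  inp$Ahyper <- warm$bundle@Ahyper
  tape <- ns$adTape()
  nodes <- lapply(P, function(x) ns$adParam(tape, x))
  fwd <- ns$.modelForward(nodes, inp, cfg, training = FALSE)
  loss <- ns$.adDceLoss(fwd$scores, pairs$label, alpha = 0.8)
  ns$adBackward(loss)
  for (e in c("m", "d")) for (v in 1:3) for (l in 1:2) {
    g <- nodes[[sprintf("homo.%s.v%d.W%d", e, v, l)]]$grad
    expect_false(is.null(g))
    expect_gt(max(abs(g)), 0)
  }
  # spot-check one weight against a finite difference
  nm <- "homo.m.v2.W1"
  i <- 5L
  lossAt <- function(val) {
    P2 <- P; P2[[nm]][i] <- val
    f <- ns$.modelForward(P2, inp, cfg, training = FALSE)
    dceLoss(pairs$label, as.numeric(f$scores), alpha = 0.8)
  }
  eps <- 1e-5
  fd <- (lossAt(P[[nm]][i] + eps) - lossAt(P[[nm]][i] - eps)) / (2 * eps)
  expect_equal(nodes[[nm]]$grad[i], fd, tolerance = 1e-3)
})
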