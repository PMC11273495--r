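# Minimal tape-based reverse-mode automatic differentiation on dense
# matrices. Every quantity is a base-R matrix (scalars are 1 x 1); ops
# accept plain matrices (returning plain matrices, used by the exported
# forward functions) or tape nodes (recording the backward closure). This
# is deliberately small: just the op set the encoders, attention layers and
# losses need, each with a hand-derived vector-Jacobian product that the
# test suite checks against central finite differences.

adTape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

isNode <- function(x) inherits(x, "ad_node")

adValue <- function(x) if (isNode(x)) x$value else x

.asMat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)

.newNode <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  nd$tape <- tape
  class(nd) <- "ad_node"
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

.tapeOf <- function(...) {
  for (x in list(...)) if (isNode(x)) return(x$tape)
  NULL
}

#' @noRd
adParam <- function(tape, value) .newNode(tape, .asMat(value))

adConst <- function(tape, value) .newNode(tape, .asMat(value))

# Run the tape backwards from a (1 x 1) loss node, accumulating gradients
# into every reachable node's $grad.
adBackward <- function(loss) {
  tape <- loss$tape
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  loss$grad <- matrix(1, nrow(loss$value), ncol(loss$value))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      if (is.null(gs[[j]]) || !isNode(ps[[j]])) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}

adMM <- function(a, b) {
  av <- adValue(a); bv <- adValue(b)
  v <- av %*% bv
  tape <- .tapeOf(a, b)
  if (is.null(tape)) return(v)
  .newNode(tape, v, list(a, b), function(g)
    list(g %*% t(bv), t(av) %*% g))
}

# Elementwise sum; the second argument may be a 1 x 1 scalar (broadcast) or
# a plain numeric constant.
adAdd <- function(a, b) {
  av <- adValue(a); bv <- adValue(b)
  bScalar <- length(bv) == 1L && length(av) > 1L
  aScalar <- length(av) == 1L && length(bv) > 1L
  v <- if (bScalar) av + as.numeric(bv)
       else if (aScalar) as.numeric(av) + bv
       else av + bv
  tape <- .tapeOf(a, b)
  if (is.null(tape)) return(v)
  .newNode(tape, v, list(a, b), function(g) list(
    if (aScalar) matrix(sum(g), 1L, 1L) else g,
    if (bScalar) matrix(sum(g), 1L, 1L) else g
  ))
}

adScale <- function(x, s) {
  xv <- adValue(x)
  v <- s * xv
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g) list(s * g))
}

adSub <- function(a, b) adAdd(a, adScale(b, -1))

# Elementwise (Hadamard) product; one argument may be 1 x 1 (broadcast).
adMul <- function(a, b) {
  av <- adValue(a); bv <- adValue(b)
  bScalar <- length(bv) == 1L && length(av) > 1L
  aScalar <- length(av) == 1L && length(bv) > 1L
  v <- if (bScalar) av * as.numeric(bv)
       else if (aScalar) as.numeric(av) * bv
       else av * bv
  tape <- .tapeOf(a, b)
  if (is.null(tape)) return(v)
  .newNode(tape, v, list(a, b), function(g) list(
    if (aScalar) matrix(sum(g * bv), 1L, 1L)
    else if (bScalar) g * as.numeric(bv) else g * bv,
    if (bScalar) matrix(sum(g * av), 1L, 1L)
    else if (aScalar) g * as.numeric(av) else g * av
  ))
}

# Scalar (1 x 1) division a / b.
adDiv <- function(a, b) {
  av <- as.numeric(adValue(a)); bv <- as.numeric(adValue(b))
  v <- matrix(av / bv, 1L, 1L)
  tape <- .tapeOf(a, b)
  if (is.null(tape)) return(v)
  .newNode(tape, v, list(a, b), function(g) list(
    matrix(as.numeric(g) / bv, 1L, 1L),
    matrix(-as.numeric(g) * av / bv^2, 1L, 1L)
  ))
}

adAddRow <- function(x, b) {
  xv <- adValue(x); bv <- adValue(b)
  v <- sweep(xv, 2L, as.numeric(bv), "+")
  tape <- .tapeOf(x, b)
  if (is.null(tape)) return(v)
  .newNode(tape, v, list(x, b), function(g)
    list(g, matrix(colSums(g), 1L)))
}

# Multiply each row i of x by w[i, 1] (column broadcast).
adMulCol <- function(x, w) {
  xv <- adValue(x); wv <- adValue(w)
  v <- xv * as.numeric(wv)
  tape <- .tapeOf(x, w)
  if (is.null(tape)) return(v)
  .newNode(tape, v, list(x, w), function(g)
    list(g * as.numeric(wv), matrix(rowSums(g * xv), ncol = 1L)))
}

adRelu <- function(x) {
  xv <- adValue(x)
  v <- pmax(xv, 0)
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g) list(g * (xv > 0)))
}

adSigmoid <- function(x) {
  xv <- adValue(x)
  v <- 1 / (1 + exp(-xv))
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g) list(g * v * (1 - v)))
}

adLog <- function(x) {
  xv <- adValue(x)
  v <- log(xv)
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g) list(g / xv))
}

adClip <- function(x, lo, hi) {
  xv <- adValue(x)
  v <- pmin(pmax(xv, lo), hi)
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g) list(g * (xv > lo & xv < hi)))
}

adSoftmaxRows <- function(x) {
  xv <- adValue(x)
  rowMax <- xv[cbind(seq_len(nrow(xv)), max.col(xv, ties.method = "first"))]
  e <- exp(xv - rowMax)
  v <- e / rowSums(e)
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g)
    list(v * (g - rowSums(g * v))))
}

# Row-wise layer normalisation with learnable gain/offset (1 x d each).
adLayerNorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- adValue(x); gv <- as.numeric(adValue(gamma)); bv <- as.numeric(adValue(beta))
  mu <- rowMeans(xv)
  va <- rowMeans((xv - mu)^2)
  sd <- sqrt(va + eps)
  xhat <- (xv - mu) / sd
  v <- sweep(xhat * rep(gv, each = nrow(xv)), 2L, bv, "+")
  tape <- .tapeOf(x, gamma, beta)
  if (is.null(tape)) return(v)
  .newNode(tape, v, list(x, gamma, beta), function(g) {
    dxhat <- g * rep(gv, each = nrow(g))
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

adT <- function(x) {
  xv <- adValue(x)
  v <- t(xv)
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g) list(t(g)))
}

adRows <- function(x, idx) {
  xv <- adValue(x)
  v <- xv[idx, , drop = FALSE]
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g) {
    z <- matrix(0, nrow(xv), ncol(xv))
    if (anyDuplicated(idx)) {
      rs <- rowsum(g, group = idx)
      z[as.integer(rownames(rs)), ] <- rs
    } else {
      z[idx, ] <- g
    }
    list(z)
  })
}

adCols <- function(x, idx) {
  xv <- adValue(x)
  v <- xv[, idx, drop = FALSE]
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g) {
    z <- matrix(0, nrow(xv), ncol(xv))
    rs <- rowsum(t(g), group = idx)
    z[, as.integer(rownames(rs))] <- t(rs)
    list(z)
  })
}

adRbind <- function(parts) {
  vs <- lapply(parts, adValue)
  v <- do.call(rbind, vs)
  tape <- do.call(.tapeOf, parts)
  if (is.null(tape)) return(v)
  ns <- vapply(vs, nrow, 1L)
  ends <- cumsum(ns)
  .newNode(tape, v, parts, function(g)
    lapply(seq_along(parts), function(i)
      g[seq(ends[i] - ns[i] + 1L, ends[i]), , drop = FALSE]))
}

adCbind <- function(parts) {
  vs <- lapply(parts, adValue)
  v <- do.call(cbind, vs)
  tape <- do.call(.tapeOf, parts)
  if (is.null(tape)) return(v)
  ns <- vapply(vs, ncol, 1L)
  ends <- cumsum(ns)
  .newNode(tape, v, parts, function(g)
    lapply(seq_along(parts), function(i)
      g[, seq(ends[i] - ns[i] + 1L, ends[i]), drop = FALSE]))
}

# Shift columns by s (positive = right) with zero fill; linear, used by the
# same-padded 1-D convolution of the scoring head.
adShiftCols <- function(x, s) {
  xv <- adValue(x)
  d <- ncol(xv)
  shift <- function(m, by) {
    z <- matrix(0, nrow(m), ncol(m))
    if (by == 0L) return(m)
    if (abs(by) >= d) return(z)
    if (by > 0L) z[, seq(by + 1L, d)] <- m[, seq_len(d - by)]
    else z[, seq_len(d + by)] <- m[, seq(1L - by, d)]
    z
  }
  v <- shift(xv, s)
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g) list(shift(g, -s)))
}

adSum <- function(x) {
  xv <- adValue(x)
  v <- matrix(sum(xv), 1L, 1L)
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g)
    list(matrix(as.numeric(g), nrow(xv), ncol(xv))))
}

adMean <- function(x) {
  xv <- adValue(x)
  v <- matrix(mean(xv), 1L, 1L)
  if (!isNode(x)) return(v)
  .newNode(x$tape, v, list(x), function(g)
    list(matrix(as.numeric(g) / length(xv), nrow(xv), ncol(xv))))
}

# Look up a learnable scalar per integer distance: B[i, j] = b[D[i, j] + 1]
# for b a 1 x (maxD + 1) parameter and D an integer distance matrix.
adGatherBias <- function(b, D) {
  bv <- as.numeric(adValue(b))
  v <- matrix(bv[D + 1L], nrow(D), ncol(D))
  if (!isNode(b)) return(v)
  .newNode(b$tape, v, list(b), function(g)
    list(matrix(vapply(seq_along(bv) - 1L,
                       function(k) sum(g[D == k]), 0), 1L)))
}
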