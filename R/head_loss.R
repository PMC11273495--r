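# Same-padded single-channel 1-D convolution along the feature axis with a
# length-3 kernel (w is 1 x 3, b a 1 x 1 bias); plain or tape mode.
.conv1d <- function(X, w, b) {
  y <- adAdd(
    adAdd(adMul(adShiftCols(X, 1L), adCols(w, 1L)),
          adMul(X, adCols(w, 2L))),
    adMul(adShiftCols(X, -1L), adCols(w, 3L))
  )
  adAdd(y, b)
}

# Two-source fusion: softmax over a 1 x 2 logit row gives the weights that
# blend an entity's homogeneous-network and hypergraph representations.
.fuseRepresentations <- function(Hhomo, Hgct, logits) {
  W <- adSoftmaxRows(logits)
  adAdd(adMul(Hhomo, adCols(W, 1L)), adMul(Hgct, adCols(W, 2L)))
}

# Head forward on already-gathered pair embeddings.
.scoreForward <- function(M, D, head) {
  cm <- .conv1d(M, head$conv_w, head$conv_b)
  cd <- .conv1d(D, head$conv_w, head$conv_b)
  h <- adMul(cm, cd)
  adSigmoid(adAdd(adMM(h, head$head_w), head$head_b))
}

#' Initialise scoring-head weights
#'
#' @param dim Embedding width E.
#' @param seed Optional seed.
#' @return List with `conv_w` (1 x 3), `conv_b`, `head_w` (E x 1), `head_b`.
#' @export
initHeadParams <- function(dim, seed = NULL) {
  .withSeed(seed, list(
    conv_w = matrix(c(0, 1, 0) + stats::rnorm(3L, sd = 0.1), 1L),
    conv_b = matrix(0, 1L, 1L),
    head_w = matrix(stats::rnorm(dim, sd = sqrt(1 / dim)), dim, 1L),
    head_b = matrix(0, 1L, 1L)
  ))
}

#' Score miRNA-disease pairs
#'
#' For each requested pair, the miRNA and disease embeddings pass through a
#' shared same-padded 1-D convolution, are combined by Hadamard product and
#' fed to a single-layer feed-forward network with sigmoid output, giving
#' an association probability strictly inside (0, 1). With all-zero final
#' weights every score is exactly 0.5.
#'
#' @param Zm,Zd Embedding matrices (km x E, kd x E).
#' @param pairs Two-column (miRNA index, disease index) matrix.
#' @param head Weight list from [initHeadParams()].
#' @return Numeric vector of scores, one per pair row.
#' @export
scorePairs <- function(Zm, Zd, pairs, head) {
  pairs <- .pairMatrix(pairs[, 1L], pairs[, 2L])
  if (nrow(pairs)) {
    if (max(pairs[, 1L]) > nrow(Zm) || max(pairs[, 2L]) > nrow(Zd))
      stop("pair index out of range")
  }
  s <- .scoreForward(Zm[pairs[, 1L], , drop = FALSE],
                     Zd[pairs[, 2L], , drop = FALSE], head)
  as.numeric(s)
}

#' Dice loss
#'
#' `1 - 2 sum(y yhat) / (sum(y) + sum(yhat))` (optionally smoothed by
#' adding `smooth` to numerator and denominator). Lies in \[0, 1\]; smaller
#' is better, 0 at perfect binary overlap.
#'
#' @param y Binary labels.
#' @param yhat Scores in \[0, 1\].
#' @param smooth Smoothing term (default 0, the plain form).
#' @return Scalar loss.
#' @export
diceLoss <- function(y, yhat, smooth = 0) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  if (min(yhat) < 0 || max(yhat) > 1) stop("yhat must lie in [0, 1]")
  den <- sum(y) + sum(yhat) + smooth
  if (den == 0) {
    if (smooth > 0) return(0)
    stop("sum(y) + sum(yhat) is zero; set smooth > 0 to define the loss")
  }
  1 - (2 * sum(y * yhat) + smooth) / den
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood with scores clipped to
#' `[eps, 1 - eps]` for numerical safety.
#'
#' @param y Binary labels.
#' @param yhat Scores in \[0, 1\].
#' @param eps Clipping bound (default 1e-7).
#' @return Scalar loss (nonnegative).
#' @export
ceLoss <- function(y, yhat, eps = 1e-7) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Combined Dice + cross-entropy (DCE) loss
#'
#' `alpha * Dice + (1 - alpha) * CE`: the convex combination balancing the
#' overlap-based objective (robust to class imbalance) against the
#' distribution-based one (fast convergence). `alpha = 1` is pure Dice,
#' `alpha = 0` pure cross-entropy; the published operating point is
#' `alpha = 0.8`.
#'
#' @param y Binary labels.
#' @param yhat Scores in \[0, 1\].
#' @param alpha Mixing weight in \[0, 1\] (default 0.8).
#' @param smooth Dice smoothing term.
#' @param eps Cross-entropy clipping bound.
#' @return Scalar loss.
#' @export
dceLoss <- function(y, yhat, alpha = 0.8, smooth = 0, eps = 1e-7) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * diceLoss(y, yhat, smooth = smooth) +
    (1 - alpha) * ceLoss(y, yhat, eps = eps)
}

# Tape-mode DCE loss on a score column node with constant labels.
.adDceLoss <- function(scores, y, alpha, smooth = 0, eps = 1e-7) {
  yc <- matrix(y, ncol = 1L)
  ce <- NULL
  if (alpha < 1) {
    l1 <- adLog(adClip(scores, eps, 1 - eps))
    l2 <- adLog(adClip(adAdd(adScale(scores, -1), 1), eps, 1 - eps))
    term <- adAdd(adMul(l1, yc), adMul(l2, 1 - yc))
    ce <- adScale(adMean(term), -1)
  }
  dice <- NULL
  if (alpha > 0) {
    num <- adAdd(adScale(adSum(adMul(scores, yc)), 2), smooth)
    den <- adAdd(adSum(scores), sum(yc) + smooth)
    dice <- adAdd(adScale(adDiv(num, den), -1), 1)
  }
  if (is.null(ce)) return(dice)
  if (is.null(dice)) return(ce)
  adAdd(adScale(dice, alpha), adScale(ce, 1 - alpha))
}
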