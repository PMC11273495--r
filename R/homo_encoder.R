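#' Symmetric GCN normalisation with self-loops
#'
#' `Ahat = D^-1/2 (A + I) D^-1/2` with `D` the degree matrix of `A + I`.
#' Self-loops guarantee positive degrees, keeping the normalisation defined
#' for isolated nodes.
#'
#' @param A Square nonnegative adjacency matrix.
#' @param selfLoops Add the identity before normalising (default `TRUE`).
#' @return Normalised adjacency of the same shape.
#' @export
gcnNormalize <- function(A, selfLoops = TRUE) {
  .assertSquare(A, "A")
  if (min(A) < 0) stop("A must be nonnegative")
  W <- if (selfLoops) A + diag(nrow(A)) else A
  d <- rowSums(W)
  d[d == 0] <- 1
  s <- 1 / sqrt(d)
  W * outer(s, s)
}

# Two-or-more layer GCN forward: H <- relu(Ahat H W) per layer, with
# optional dropout between layers. Works on plain matrices or tape nodes.
.gcnForward <- function(Ahat, X0, weights, dropout = 0, training = FALSE) {
  H <- X0
  for (l in seq_along(weights)) {
    H <- adRelu(adMM(Ahat, adMM(H, weights[[l]])))
    if (training && dropout > 0 && l < length(weights))
      H <- .adDropout(H, dropout)
  }
  H
}

.adDropout <- function(x, rate) {
  if (rate <= 0) return(x)
  v <- adValue(x)
  mask <- matrix((stats::runif(length(v)) >= rate) / (1 - rate),
                 nrow(v), ncol(v))
  adMul(x, mask)
}

#' Encode one similarity view with a GCN
#'
#' Stacked graph-convolution layers `H^(r+1) = ReLU(Ahat H^(r) W^(r))` over
#' the (masked) similarity adjacency, with self-loops and symmetric
#' normalisation.
#'
#' @param Amask Square symmetric adjacency (e.g. [maskedAdjacency()]).
#' @param X0 Initial node features (n x d0), typically a learned projection
#'   of one-hot node identities.
#' @param weights List of layer weight matrices (d0 x d, then d x d).
#' @return Node-embedding matrix (n x ncol of the last weight).
#' @export
gcnViewEncode <- function(Amask, X0, weights) {
  .assertSymmetric(Amask, what = "Amask")
  if (!is.list(weights)) weights <- list(weights)
  if (nrow(X0) != nrow(Amask)) stop("X0 rows must match Amask dimension")
  .gcnForward(gcnNormalize(Amask), X0, weights)
}

# Shared view-attention machinery (plain or tape mode): per-node scores via
# a shared scoring vector, softmax over views, convex per-node combination.
.attentionFuse <- function(perView, score) {
  if (length(perView) == 1L) {
    n <- nrow(adValue(perView[[1L]]))
    return(list(fused = perView[[1L]], weights = matrix(1, n, 1L)))
  }
  S <- adCbind(lapply(perView, function(H) adMM(H, score)))
  W <- adSoftmaxRows(S)
  fused <- NULL
  for (v in seq_along(perView)) {
    term <- adMulCol(perView[[v]], adCols(W, v))
    fused <- if (is.null(fused)) term else adAdd(fused, term)
  }
  list(fused = fused, weights = W)
}

#' Fuse per-view embeddings with node-level attention
#'
#' Each node gets a softmax-normalised weight per view, scored by a shared
#' scoring vector applied to that view's embedding of the node; the fused
#' embedding is the per-node convex combination of the views. With a single
#' view the weight is 1 and the view passes through.
#'
#' @param perView Named list of equal-shape embedding matrices (n x d).
#' @param score Scoring vector (d x 1). Equal logits give equal weights.
#' @return List with `fused` (n x d), `weights` (n x V simplex rows) and
#'   `perView` (the input).
#' @export
attentionFuseViews <- function(perView, score = NULL) {
  if (!length(perView)) stop("at least one view required")
  dims <- vapply(perView, function(H) paste(dim(H), collapse = "x"), "")
  if (length(unique(dims)) != 1L) stop("view embeddings must share shape")
  if (is.null(score)) score <- matrix(0, ncol(perView[[1L]]), 1L)
  out <- .attentionFuse(perView, score)
  list(fused = out$fused, weights = adValue(out$weights), perView = perView)
}
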