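#' Cosine coupling weights between entities and supernodes
#'
#' `C[i, k] = x_i . q_k / (||x_i|| ||q_k||)`; rows with zero norm get
#' weight 0 by convention. Scale-invariant in both arguments.
#'
#' @param X Entity embedding matrix (n x E).
#' @param Q Supernode embedding matrix (q x E).
#' @return n x q matrix of cosines in \[-1, 1\].
#' @export
cosineWeights <- function(X, Q) {
  if (ncol(X) != ncol(Q)) stop("embedding dimensions must agree")
  nx <- sqrt(rowSums(X^2))
  nq <- sqrt(rowSums(Q^2))
  C <- tcrossprod(X, Q)
  den <- outer(nx, nq)
  C <- ifelse(den > 0, C / den, 0)
  matrix(pmin(1, pmax(-1, C)), nrow(X), nrow(Q))
}

#' Assemble the supernode heterogeneous hypergraph
#'
#' Builds the joint adjacency over `km + kd + q` nodes: every supernode is
#' coupled to every miRNA and disease node with weight `ReLU(cosine)`
#' (negative cosines are clipped so the adjacency stays nonnegative);
#' the miRNA-disease block carries the *training* positives only, at weight
#' 1; within-type blocks stay empty. Passing the held-out pairs via
#' `forbiddenPairs` arms a leakage guard that errors if any of them appears
#' among `knownPairs`.
#'
#' @param Xm,Xd,Q Embedding matrices (km x E, kd x E, q x E).
#' @param knownPairs Two-column (miRNA, disease) index matrix of training
#'   positives.
#' @param forbiddenPairs Optional held-out pair matrix for the guard.
#' @return A [HypergraphBundle-class].
#' @export
assembleHypergraph <- function(Xm, Xd, Q, knownPairs = NULL,
                               forbiddenPairs = NULL) {
  km <- nrow(Xm); kd <- nrow(Xd); q <- nrow(Q)
  if (is.null(knownPairs)) knownPairs <- .emptyPairs()
  knownPairs <- .pairMatrix(knownPairs[, 1L], knownPairs[, 2L])
  if (!is.null(forbiddenPairs) && nrow(knownPairs) && nrow(forbiddenPairs)) {
    keyK <- paste(knownPairs[, 1L], knownPairs[, 2L])
    keyF <- paste(forbiddenPairs[, 1L], forbiddenPairs[, 2L])
    leak <- intersect(keyK, keyF)
    if (length(leak))
      stop("leakage guard: held-out pair(s) found among hypergraph edges: ",
           paste(utils::head(leak, 3L), collapse = "; "))
  }
  Cmq <- cosineWeights(Xm, Q)
  Cdq <- cosineWeights(Xd, Q)
  n <- km + kd + q
  A <- matrix(0, n, n)
  if (nrow(knownPairs)) {
    idx <- cbind(knownPairs[, 1L], km + knownPairs[, 2L])
    A[idx] <- 1
    A[idx[, 2:1, drop = FALSE]] <- 1
  }
  sup <- km + kd + seq_len(q)
  A[seq_len(km), sup] <- pmax(Cmq, 0)
  A[sup, seq_len(km)] <- t(pmax(Cmq, 0))
  A[km + seq_len(kd), sup] <- pmax(Cdq, 0)
  A[sup, km + seq_len(kd)] <- t(pmax(Cdq, 0))
  new("HypergraphBundle", Xm = Xm, Xd = Xd, Q = Q,
      Cmq = Cmq, Cdq = Cdq, Ahyper = A)
}

#' Capped all-pairs shortest-path (hop) matrix
#'
#' Hop distances on the unweighted support of the adjacency (edge iff
#' weight > 0), capped at `maxSp`; unreachable pairs score the cap. Used as
#' the spatial bias of the self-attention.
#'
#' @param A Symmetric nonnegative adjacency matrix.
#' @param maxSp Distance cap (default 8, the maximum path length).
#' @return Integer matrix with zero diagonal, symmetric, entries in
#'   \[0, maxSp\].
#' @export
shortestPathMatrix <- function(A, maxSp = 8L) {
  .assertSymmetric(A, what = "A")
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  D <- igraph::distances(g)
  D[!is.finite(D)] <- maxSp
  D <- pmin(D, maxSp)
  storage.mode(D) <- "integer"
  D
}

# One scaled-dot-product attention head with an additive matrix bias inside
# the softmax; plain or tape mode.
.attentionHead <- function(H, Wq, Wk, Wv, bias) {
  Qh <- adMM(H, Wq); Kh <- adMM(H, Wk); Vh <- adMM(H, Wv)
  dk <- ncol(adValue(Wq))
  logits <- adAdd(adScale(adMM(Qh, adT(Kh)), 1 / sqrt(dk)), bias)
  probs <- adSoftmaxRows(logits)
  list(output = adMM(probs, Vh), attention = probs)
}

# Multi-head attention: full-width Wq/Wk/Wv split into per-head column
# blocks, concatenated head outputs projected by WO. The distance bias is
# shared across heads.
.multiHeadAttention <- function(H, Wq, Wk, Wv, WO, bias, heads) {
  E <- ncol(adValue(Wq))
  if (E %% heads != 0) stop("attention heads must divide the model dimension")
  dk <- E %/% heads
  outs <- vector("list", heads)
  atts <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    head <- .attentionHead(H, adCols(Wq, cols), adCols(Wk, cols),
                           adCols(Wv, cols), bias)
    outs[[h]] <- head$output
    atts[[h]] <- adValue(head$attention)
  }
  list(output = adMM(adCbind(outs), WO), attention = atts)
}

#' Shortest-path-biased multi-head self-attention
#'
#' Scaled dot-product self-attention whose logits receive an additive bias
#' derived from inter-node hop distances before the softmax:
#' `softmax(Q K^T / sqrt(dk) + B) V` per head, heads concatenated and
#' projected by `WO`. With `biasMode = "embedding"` (default) the bias is a
#' scalar per integer distance taken from `distanceBias` (a vector of
#' length `maxSp + 1`), so nearer nodes can be favoured; `"raw"` adds the
#' hop count itself, the literal reading of the bias term.
#'
#' @param H Node feature matrix (n x E).
#' @param Wq,Wk,Wv Full-width projection matrices (E x E), split across
#'   heads by column blocks.
#' @param WO Output projection (E x E).
#' @param D Integer hop-distance matrix from [shortestPathMatrix()].
#' @param heads Number of attention heads (must divide E).
#' @param distanceBias Numeric vector of per-distance scalars
#'   (`biasMode = "embedding"`).
#' @param biasMode `"embedding"` or `"raw"`.
#' @return List with `output` (n x E) and `attention` (list of per-head
#'   row-stochastic matrices).
#' @export
spBiasedAttention <- function(H, Wq, Wk, Wv, WO, D, heads = 4L,
                              distanceBias = NULL,
                              biasMode = c("embedding", "raw")) {
  biasMode <- match.arg(biasMode)
  if (any(!is.finite(adValue(H)))) stop("NaN/Inf in attention input")
  bias <- if (biasMode == "raw") {
    matrix(as.numeric(D), nrow(D), ncol(D))
  } else {
    if (is.null(distanceBias)) distanceBias <- -0.3 * (0:max(D))
    adGatherBias(.asMat(distanceBias), D)
  }
  .multiHeadAttention(H, Wq, Wk, Wv, WO, bias, heads)
}

# One full GCN-Transformer encoder layer (plain or tape mode). `params` is
# the per-layer weight list; `bias` the (node or matrix) attention bias.
.gctLayerForward <- function(H, Ahat, bias, params, heads,
                             dropout = 0, training = FALSE, plainGcn = FALSE) {
  G <- adRelu(adMM(Ahat, adMM(H, params$Wg)))
  if (plainGcn) return(G)
  att <- .multiHeadAttention(G, params$Wq, params$Wk, params$Wv, params$WO,
                             bias, heads)
  upd <- att$output
  if (training && dropout > 0) upd <- .adDropout(upd, dropout)
  R1 <- adLayerNorm(adAdd(G, upd), params$ln1g, params$ln1b)
  FF <- adAddRow(adMM(adRelu(adAddRow(adMM(R1, params$F1), params$b1)),
                      params$F2), params$b2)
  if (training && dropout > 0) FF <- .adDropout(FF, dropout)
  out <- adLayerNorm(adAdd(R1, FF), params$ln2g, params$ln2b)
  attr(out, "attention") <- att$attention
  out
}

#' Random initial weights for one GCN-Transformer encoder layer
#'
#' Glorot-scaled normal weights for the GCN sublayer, the per-head
#' attention projections, the output projection and the position-wise
#' feed-forward, plus unit/zero layer-norm gains and offsets.
#'
#' @param dim Model (embedding) width E.
#' @param ffnHidden Feed-forward hidden width.
#' @param seed Optional seed.
#' @return Named list of weight matrices.
#' @export
initGctLayerParams <- function(dim, ffnHidden = 2048L, seed = NULL) {
  .withSeed(seed, {
    gl <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)
    list(
      Wg = gl(dim, dim), Wq = gl(dim, dim), Wk = gl(dim, dim),
      Wv = gl(dim, dim), WO = gl(dim, dim),
      F1 = gl(dim, ffnHidden), b1 = matrix(0, 1L, ffnHidden),
      F2 = gl(ffnHidden, dim), b2 = matrix(0, 1L, dim),
      ln1g = matrix(1, 1L, dim), ln1b = matrix(0, 1L, dim),
      ln2g = matrix(1, 1L, dim), ln2b = matrix(0, 1L, dim)
    )
  })
}

#' One GCN-Transformer encoder layer
#'
#' A GCN sublayer `ReLU(Ahat H Wg)` feeds multi-head shortest-path-biased
#' self-attention; a residual connection and row-wise layer normalisation
#' follow, then a position-wise feed-forward block with its own residual
#' and layer normalisation. Output shape equals input shape.
#'
#' @param H Node features (n x E).
#' @param Ahyper Hypergraph adjacency (normalised internally).
#' @param D Hop-distance matrix from [shortestPathMatrix()].
#' @param params Layer weights from [initGctLayerParams()].
#' @param heads Number of attention heads.
#' @param distanceBias Per-distance bias scalars (see [spBiasedAttention()]).
#' @param biasMode `"embedding"` or `"raw"`.
#' @return n x E matrix with attribute `"attention"` (per-head matrices).
#' @export
gctEncoderLayer <- function(H, Ahyper, D, params, heads = 4L,
                            distanceBias = NULL,
                            biasMode = c("embedding", "raw")) {
  biasMode <- match.arg(biasMode)
  if (ncol(H) %% heads != 0) stop("attention heads must divide the model dimension")
  bias <- if (biasMode == "raw") matrix(as.numeric(D), nrow(D), ncol(D))
          else {
            if (is.null(distanceBias)) distanceBias <- -0.3 * (0:max(D))
            adGatherBias(.asMat(distanceBias), D)
          }
  .gctLayerForward(H, gcnNormalize(Ahyper), bias, params, heads)
}

#' Encode miRNA and disease nodes on the shared hypergraph
#'
#' Runs the stacked GCN-Transformer layers jointly over miRNA, disease and
#' supernode rows of the assembled hypergraph, then splits the result back
#' into the two entity families (supernode rows are updated but not
#' returned).
#'
#' @param bundle A [HypergraphBundle-class].
#' @param layerParams List of per-layer weight lists
#'   ([initGctLayerParams()]).
#' @param heads,maxSp,distanceBias,biasMode Attention settings.
#' @return List with `Zm` (km x E), `Zd` (kd x E) and `Zq` (q x E).
#' @export
gctEncode <- function(bundle, layerParams, heads = 4L, maxSp = 8L,
                      distanceBias = NULL,
                      biasMode = c("embedding", "raw")) {
  biasMode <- match.arg(biasMode)
  km <- nrow(bundle@Xm); kd <- nrow(bundle@Xd)
  H <- rbind(bundle@Xm, bundle@Xd, bundle@Q)
  D <- shortestPathMatrix(bundle@Ahyper, maxSp = maxSp)
  Ahat <- gcnNormalize(bundle@Ahyper)
  bias <- if (biasMode == "raw") matrix(as.numeric(D), nrow(D), ncol(D))
          else {
            if (is.null(distanceBias)) distanceBias <- -0.3 * (0:maxSp)
            adGatherBias(.asMat(distanceBias), D)
          }
  for (params in layerParams)
    H <- .gctLayerForward(H, Ahat, bias, params, heads)
  list(
    Zm = H[seq_len(km), , drop = FALSE],
    Zd = H[km + seq_len(kd), , drop = FALSE],
    Zq = H[km + kd + seq_len(nrow(bundle@Q)), , drop = FALSE]
  )
}
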