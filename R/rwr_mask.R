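#' Sample random-walk start nodes
#'
#' Each of the `n` nodes is included independently with probability `p`
#' (Bernoulli sampling), giving the start-node set of the masking strategy.
#'
#' @param n Number of nodes.
#' @param p Sampling rate in \[0, 1\] (the strategy mask ratio; default 0.3).
#' @param seed Optional integer seed.
#' @return Integer vector of sampled node indices.
#' @export
sampleStartNodes <- function(n, p = 0.3, seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  .withSeed(seed, which(stats::runif(n) < p))
}

#' Restart-augmented random-walk transition matrix
#'
#' `P = (1 - c) D^-1 A + c I`, where `D` is the diagonal degree matrix of
#' `A`. Rows of isolated nodes (zero degree) are set to a unit self-loop so
#' `P` stays row-stochastic. The restart probability is attached as
#' `attr(P, "restart")` for use by [extractPath()]. Edges at or below
#' `threshold` are dropped before normalisation.
#'
#' @param A Square nonnegative (similarity) matrix.
#' @param c Restart probability in \[0, 1\] (default 0.6).
#' @param threshold Edge weights `<= threshold` are excluded (default 0:
#'   keep all positive weights).
#' @return Row-stochastic matrix with attribute `restart`.
#' @examples
#' rwrTransitionMatrix(matrix(c(0, 1, 1, 0), 2), c = 0.6)
#' @export
rwrTransitionMatrix <- function(A, c = 0.6, threshold = 0) {
  .assertSquare(A, "A")
  if (min(A) < 0) stop("A must be nonnegative")
  if (c < 0 || c > 1) stop("restart probability c must lie in [0, 1]")
  W <- A
  W[W <= threshold] <- 0
  deg <- rowSums(W)
  P <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  pos <- deg > 0
  if (any(pos)) P[pos, ] <- (1 - c) * W[pos, , drop = FALSE] / deg[pos]
  diag(P) <- diag(P) + c
  diag(P)[!pos] <- 1
  attr(P, "restart") <- c
  P
}

#' Extract one restart-enabled random-walk path
#'
#' Walks `k` steps from `start`. At each step the walker restarts to the
#' start node with probability `c` (the restart event is recorded in the
#' sequence as the start node, so paths always have `k + 1` entries);
#' otherwise it moves to a neighbour drawn from the degree-normalised edge
#' weights of the current node.
#'
#' @param P Transition matrix from [rwrTransitionMatrix()].
#' @param start Start node index.
#' @param k Number of steps (path length).
#' @param seed Optional integer seed.
#' @param c Restart probability; defaults to `attr(P, "restart")`.
#' @return Integer vector of `k + 1` node indices beginning with `start`.
#' @export
extractPath <- function(P, start, k = 8L, seed = NULL, c = attr(P, "restart")) {
  .assertSquare(P, "P")
  if (is.null(c)) stop("restart probability not supplied and not found on P")
  if (k < 0) stop("k must be >= 0")
  n <- nrow(P)
  if (start < 1L || start > n) stop("start node out of range")
  # Per-row neighbour distribution with the restart mass removed.
  .withSeed(seed, {
    path <- integer(k + 1L)
    path[[1L]] <- cur <- as.integer(start)
    if (k > 0L) for (s in seq_len(k)) {
      if (stats::runif(1L) < c) {
        cur <- as.integer(start)
      } else {
        w <- P[cur, ]
        w[cur] <- w[cur] - c
        w[w < 0] <- 0
        if (sum(w) <= 0) {
          cur <- as.integer(start)  # isolated node: only the restart remains
        } else {
          cur <- sample.int(n, 1L, prob = w)
        }
      }
      path[[s + 1L]] <- cur
    }
    path
  })
}

#' Binary membership mask of a walk
#'
#' Entry `j` is 1 iff node `j` occurs anywhere in the path.
#'
#' @param path Integer node sequence.
#' @param n Number of nodes.
#' @return Binary vector of length `n`.
#' @export
pathMaskVector <- function(path, n) {
  if (length(path) && max(path) > n) stop("path entries must be < n")
  v <- numeric(n)
  v[path] <- 1
  v
}

#' Apply path masks to an adjacency matrix
#'
#' The coverage of the mask vectors is the elementwise union of their outer
#' products `m m^T` (symmetrised, so undirected graphs stay undirected). In
#' `"complement"` mode (the default) covered entries are zeroed - the
#' masking-as-augmentation reading, removing a random subset of network
#' connections; in `"literal"` mode only covered entries are kept
#' (elementwise product with the coverage). The two modes partition `A`:
#' literal + complement = A.
#'
#' @param A Square matrix.
#' @param maskVectors List of binary vectors from [pathMaskVector()]; an
#'   empty list returns `A` unchanged.
#' @param mode `"complement"` or `"literal"`.
#' @param paths,startNodes Optional records stored on the result.
#' @return A [MaskedGraph-class].
#' @export
applyAssociationMask <- function(A, maskVectors,
                                 mode = c("complement", "literal"),
                                 paths = list(), startNodes = integer(0)) {
  mode <- match.arg(mode)
  .assertSquare(A, "A")
  n <- nrow(A)
  if (!length(maskVectors))  # nothing sampled: graph passes through untouched
    return(new("MaskedGraph", Amask = A, maskedEntries = .emptyPairs(),
               paths = paths, startNodes = as.integer(startNodes)))
  cover <- matrix(FALSE, n, n)
  for (m in maskVectors) {
    if (length(m) != n) stop("mask vector length must match A")
    on <- m != 0
    cover[on, on] <- TRUE
  }
  cover <- cover | t(cover)
  Amask <- A
  if (mode == "complement") Amask[cover] <- 0 else Amask[!cover] <- 0
  changed <- which(A != 0 & Amask == 0, arr.ind = TRUE)
  new("MaskedGraph",
    Amask = Amask,
    maskedEntries = .pairMatrix(changed[, 1L], changed[, 2L]),
    paths = paths,
    startNodes = as.integer(startNodes)
  )
}

#' Mask a similarity view with restart-based random walks
#'
#' One full round of the association-masking strategy on a single
#' homogeneous similarity network: Bernoulli-sample start nodes, walk `k`
#' steps with restart probability `c` from each, convert the walks to
#' membership masks and apply their joint coverage to the adjacency.
#'
#' @param A Square similarity matrix.
#' @param p Start-node sampling rate (default 0.3).
#' @param c Restart probability (default 0.6).
#' @param k Maximum path length (default 8).
#' @param mode Masking mode, `"complement"` (default) or `"literal"`.
#' @param threshold Edge threshold passed to [rwrTransitionMatrix()].
#' @param seed Optional integer seed controlling the whole round.
#' @return A [MaskedGraph-class].
#' @export
maskSimilarityView <- function(A, p = 0.3, c = 0.6, k = 8L,
                               mode = c("complement", "literal"),
                               threshold = 0, seed = NULL) {
  mode <- match.arg(mode)
  .withSeed(seed, {
    S <- sampleStartNodes(nrow(A), p)
    if (!length(S))
      return(applyAssociationMask(A, list(), mode = mode))
    P <- rwrTransitionMatrix(A, c = c, threshold = threshold)
    paths <- lapply(S, function(v) extractPath(P, v, k = k))
    names(paths) <- as.character(S)
    masks <- lapply(paths, pathMaskVector, n = nrow(A))
    applyAssociationMask(A, masks, mode = mode, paths = paths, startNodes = S)
  })
}
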