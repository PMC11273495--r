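# Shared fixtures and independent reference implementations used as
# oracles. Everything here is deliberately naive (loops, closed forms) and
# independent of the package internals it checks.

# Small random symmetric similarity-like matrix with unit diagonal.
randomSimilarity <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

randomBinaryMatrix <- function(nr, nc, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rbinom(nr * nc, 1, p), nr, nc)
}

# O(n^3) Floyd-Warshall on the unweighted support, capped.
floydWarshall <- function(A, cap) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0 & row(A) != col(A)] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D[!is.finite(D)] <- cap
  pmin(D, cap)
}

# Quadratic-time Mann-Whitney AUC over all positive-negative pairs.
bruteForceAuc <- function(labels, scores) {
  p <- scores[labels == 1]
  q <- scores[labels == 0]
  tot <- 0
  for (a in p) tot <- tot + sum(a > q) + 0.5 * sum(a == q)
  tot / (length(p) * length(q))
}

# Brute-force GIP kernel, one pair at a time.
bruteForceGip <- function(A) {
  P <- A
  gamma <- 1 / mean(rowSums(P^2))
  n <- nrow(P)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  diag(K) <- 1
  K
}

# Recursive Wang semantic contribution (memo-free, tiny DAGs only).
bruteForceWang <- function(edges, decay) {
  nodes <- sort(unique(c(edges$child, edges$parent)))
  parentsOf <- function(x) edges$parent[edges$child == x]
  contrib <- function(d) {
    S <- c()
    visit <- function(node, val) {
      if (is.null(S[node]) || is.na(S[node]) || S[node] < val)
        S[node] <<- val
      for (p in parentsOf(node)) visit(p, val * decay)
    }
    visit(d, 1)
    S
  }
  cs <- lapply(stats::setNames(nodes, nodes), contrib)
  n <- length(nodes)
  M <- diag(1, n)
  dimnames(M) <- list(nodes, nodes)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    sa <- cs[[a]]; sb <- cs[[b]]
    sh <- intersect(names(sa), names(sb))
    M[a, b] <- if (length(sh)) (sum(sa[sh]) + sum(sb[sh])) / (sum(sa) + sum(sb)) else 0
  }
  M
}

# Random DAG as a child -> parent edge table (layered, guaranteed acyclic).
randomDag <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("n%02d", seq_len(n))
  edges <- NULL
  for (i in seq(2L, n)) {
    nPar <- sample(1:min(2L, i - 1L), 1L)
    for (p in sample(seq_len(i - 1L), nPar))
      edges <- rbind(edges, data.frame(child = labels[i], parent = labels[p]))
  }
  edges
}

# A small labelled dataset + views for fast training tests.
miniFixture <- function(seed = 7L) {
  sim <- generateSynthetic(syntheticSpec(km = 30L, kd = 20L, rank = 3L,
                                         seed = seed))
  list(sim = sim, ds = sampleNegatives(sim$ds, seed = seed))
}

miniConfig <- function(...) {
  args <- utils::modifyList(
    list(dim = 8L, heads = 2L, ffnHidden = 16L, supernodes = 4L,
         homoDropout = 0.1, gctDropout = 0.1, lr = 5e-3, epochs = 8L,
         seed = 1L),
    list(...))
  do.call(modelConfig, args)
}

# The desk-scale configuration the package uses for the synthetic
# benchmark: the published architecture shrunk to the fixture size.
deskConfig <- function(...) {
  args <- utils::modifyList(
    list(dim = 32L, ffnHidden = 128L, supernodes = 16L,
         homoDropout = 0.1, gctDropout = 0.1, weightDecay = 1e-4,
         lr = 5e-3, epochs = 300L, seed = 1L),
    list(...))
  do.call(modelConfig, args)
}
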