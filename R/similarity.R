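#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes the GIP kernel over the binary interaction profiles of a
#' bipartite association matrix: `K(i, j) = exp(-gamma * ||IP(i) - IP(j)||^2)`
#' with the bandwidth `gamma` set to the reciprocal of the mean squared
#' profile norm, so the kernel adapts to the overall interaction density.
#'
#' @param A Binary association matrix.
#' @param axis `"rows"` to compare row profiles (miRNAs), `"columns"` for
#'   column profiles (diseases).
#' @return Symmetric matrix with unit diagonal and entries in (0, 1\].
#' @examples
#' gipSimilarity(diag(2))  # off-diagonal exp(-2)
#' @export
gipSimilarity <- function(A, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  if (!is.matrix(A)) A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) stop("A must be binary")
  P <- if (axis == "rows") A else t(A)
  ids <- rownames(P)
  norms2 <- rowSums(P^2)
  if (all(norms2 == 0))
    stop("all interaction profiles are zero; the GIP bandwidth is undefined ",
         "(add pseudo-associations or skip this view)")
  gamma <- 1 / mean(norms2)
  G <- tcrossprod(P)
  d2 <- outer(norms2, norms2, "+") - 2 * G
  d2[d2 < 0] <- 0  # numerical guard
  K <- exp(-gamma * d2)
  diag(K) <- 1
  dimnames(K) <- list(ids, ids)
  K
}

.parseEdgeDf <- function(dag) {
  if (is.matrix(dag)) dag <- as.data.frame(dag, stringsAsFactors = FALSE)
  if (ncol(dag) < 2L) stop("DAG edge table needs two columns (child, parent)")
  data.frame(
    child = .normalizeId(as.character(dag[[1L]])),
    parent = .normalizeId(as.character(dag[[2L]])),
    stringsAsFactors = FALSE
  )
}

# Kahn topological sort over child -> parent edges; children come first.
# Errors with an offending node if a cycle exists.
.topoOrder <- function(nodes, edges) {
  parentsOf <- split(edges$parent, factor(edges$child, levels = nodes))
  childrenOf <- split(edges$child, factor(edges$parent, levels = nodes))
  indeg <- vapply(childrenOf, length, 1L)  # children still unplaced
  queue <- nodes[indeg == 0L]
  order <- character(0)
  indeg <- stats::setNames(as.integer(indeg), nodes)
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, u)
    for (p in parentsOf[[u]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order) < length(nodes))
    stop("cycle detected in disease DAG at node '",
         setdiff(nodes, order)[[1L]], "'")
  order
}

# Semantic contribution of every ancestor of `d` (Wang measure): the term
# for d itself is 1 and each parent hop multiplies by `decay`, keeping the
# best (max) contribution over paths.
.semanticContributions <- function(d, nodes, parentsOf, order, decay) {
  S <- stats::setNames(rep(-Inf, length(nodes)), nodes)
  S[[d]] <- 1
  for (u in order) {
    if (S[[u]] == -Inf) next
    for (p in parentsOf[[u]])
      S[[p]] <- max(S[[p]], decay * S[[u]])
  }
  S[S > -Inf]
}

#' Disease semantic similarity over an ontology DAG
#'
#' Wang-style semantic similarity: each disease contributes 1 to itself and
#' `decay^h` to an ancestor `h` hops up (best path), and two diseases are
#' compared by the summed contributions of their shared ancestors relative
#' to their total semantic values. Diseases absent from the DAG get an
#' all-zero row/column (unit diagonal) so the view stays well formed.
#'
#' @param dag Two-column child/parent edge table (data frame or matrix).
#' @param ids Diseases to score; defaults to every node in the DAG, sorted.
#' @param decay Semantic-contribution decay per hop, in (0, 1); default 0.5.
#' @return Symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
diseaseSemanticSimilarity <- function(dag, ids = NULL, decay = 0.5) {
  if (decay <= 0 || decay >= 1) stop("decay must lie strictly in (0, 1)")
  edges <- .parseEdgeDf(dag)
  nodes <- sort(unique(c(edges$child, edges$parent)))
  order <- .topoOrder(nodes, edges)
  parentsOf <- split(edges$parent, factor(edges$child, levels = nodes))
  if (is.null(ids)) ids <- nodes else ids <- .normalizeId(ids)
  contrib <- lapply(stats::setNames(ids, ids), function(d) {
    if (!d %in% nodes) return(NULL)
    .semanticContributions(d, nodes, parentsOf, order, decay)
  })
  dv <- vapply(contrib, function(s) if (is.null(s)) 0 else sum(s), 0)
  n <- length(ids)
  M <- diag(1, n)
  dimnames(M) <- list(ids, ids)
  if (n < 2L) return(M)
  for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
    sa <- contrib[[a]]; sb <- contrib[[b]]
    if (is.null(sa) || is.null(sb)) next
    shared <- intersect(names(sa), names(sb))
    if (!length(shared)) next
    M[a, b] <- M[b, a] <- (sum(sa[shared]) + sum(sb[shared])) / (dv[[a]] + dv[[b]])
  }
  M
}

#' miRNA functional similarity from disease semantics
#'
#' Best-match average (MISIM-style): the similarity of two miRNAs is the
#' mean, over the diseases each is associated with, of the best semantic
#' match in the other miRNA's disease set. A miRNA with no associated
#' disease keeps a unit self-similarity and zeros elsewhere.
#'
#' @param diseaseSem Square disease semantic similarity matrix.
#' @param A Binary miRNA x disease association matrix.
#' @return Symmetric km x km matrix with unit diagonal, entries in \[0, 1\].
#' @export
mirnaFunctionalSimilarity <- function(diseaseSem, A) {
  .assertSymmetric(diseaseSem, what = "diseaseSem")
  if (!is.matrix(A)) A <- as.matrix(A)
  if (ncol(A) != nrow(diseaseSem))
    stop("ncol(A) must match dim(diseaseSem)")
  km <- nrow(A)
  sets <- lapply(seq_len(km), function(i) which(A[i, ] == 1))
  M <- diag(1, km)
  dimnames(M) <- list(rownames(A), rownames(A))
  if (km < 2L) return(M)
  for (a in seq_len(km - 1L)) {
    Da <- sets[[a]]
    if (!length(Da)) next
    for (b in seq(a + 1L, km)) {
      Db <- sets[[b]]
      if (!length(Db)) next
      S <- diseaseSem[Da, Db, drop = FALSE]
      M[a, b] <- M[b, a] <-
        (sum(apply(S, 1L, max)) + sum(apply(S, 2L, max))) /
        (length(Da) + length(Db))
    }
  }
  M
}

#' miRNA sequence similarity by normalised global alignment
#'
#' Scores each pair with a global (Needleman-Wunsch) alignment under a
#' configurable scheme (default match = 1, mismatch = 0, free gaps, i.e.
#' longest-common-subsequence scoring) and normalises by the self-alignment
#' scores: `sim = 2 s(a, b) / (s(a, a) + s(b, b))`.
#'
#' @param seqs Named character vector of RNA/DNA sequences over A, C, G, U, T.
#' @param match,mismatch Substitution scores.
#' @param gapOpening,gapExtension Gap penalties (nonnegative costs).
#' @return Symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
mirnaSequenceSimilarity <- function(seqs, match = 1, mismatch = 0,
                                    gapOpening = 0, gapExtension = 0) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("mirna%03d", seq_along(seqs))
  seqs <- toupper(vapply(seqs, as.character, ""))
  bad <- grepl("[^ACGUT]", seqs)
  if (any(bad))
    stop("invalid character in sequence '", names(seqs)[bad][[1L]], "'")
  if (any(!nzchar(seqs))) stop("empty sequence for '",
                               names(seqs)[!nzchar(seqs)][[1L]], "'")
  dna <- Biostrings::DNAStringSet(chartr("U", "T", seqs))
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  n <- length(dna)
  selfScore <- match * nchar(seqs)
  M <- diag(1, n)
  dimnames(M) <- list(names(seqs), names(seqs))
  if (n < 2L) return(M)
  for (a in seq_len(n - 1L)) {
    sc <- Biostrings::pairwiseAlignment(
      rep(dna[a], n - a), dna[seq(a + 1L, n)],
      substitutionMatrix = sub, gapOpening = gapOpening,
      gapExtension = gapExtension, type = "global", scoreOnly = TRUE)
    den <- selfScore[a] + selfScore[seq(a + 1L, n)]
    M[a, seq(a + 1L, n)] <- M[seq(a + 1L, n), a] <-
      pmin(1, pmax(0, 2 * sc / den))
  }
  M
}

#' Disease target-set similarity (Jaccard)
#'
#' Jaccard index over per-disease gene sets; a pair with two empty sets
#' scores 0 and self-similarity is forced to 1.
#'
#' @param geneSets Named list of character vectors (disease -> gene set).
#' @return Symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
diseaseTargetSimilarity <- function(geneSets) {
  ids <- names(geneSets)
  if (is.null(ids)) ids <- sprintf("disease%03d", seq_along(geneSets))
  sets <- lapply(geneSets, unique)
  n <- length(sets)
  M <- diag(1, n)
  dimnames(M) <- list(ids, ids)
  if (n < 2L) return(M)
  for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
    u <- length(union(sets[[a]], sets[[b]]))
    if (u == 0L) next
    M[a, b] <- M[b, a] <- length(intersect(sets[[a]], sets[[b]])) / u
  }
  M
}

#' Derive disease gene sets through associated miRNAs' targets
#'
#' A disease inherits the union of the target genes of every miRNA it is
#' associated with, turning a miRNA -> target map into the per-disease gene
#' sets consumed by [diseaseTargetSimilarity()].
#'
#' @param A Binary miRNA x disease association matrix.
#' @param mirnaTargets List of character vectors parallel to the rows of
#'   `A` (or named by miRNA id).
#' @return Named list of gene sets, one per column of `A`.
#' @export
diseaseGeneSets <- function(A, mirnaTargets) {
  if (!is.matrix(A)) A <- as.matrix(A)
  if (!is.null(names(mirnaTargets)) && !is.null(rownames(A)))
    mirnaTargets <- mirnaTargets[rownames(A)]
  if (length(mirnaTargets) != nrow(A))
    stop("mirnaTargets must have one entry per miRNA")
  sets <- lapply(seq_len(ncol(A)), function(j) {
    sort(unique(unlist(mirnaTargets[A[, j] == 1], use.names = FALSE)))
  })
  names(sets) <- colnames(A)
  sets
}

#' Read a two-column map file (child/parent DAG or miRNA/target sets)
#'
#' @param path Two-column TSV path.
#' @return For [readDiseaseDag()], a child/parent data frame; for
#'   [readTargetSets()], a named list of character vectors.
#' @export
readDiseaseDag <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("child", "parent"))
  .parseEdgeDf(df)
}

#' @rdname readDiseaseDag
#' @export
readTargetSets <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("mirna", "gene"))
  split(as.character(df$gene), .normalizeId(df$mirna))
}

#' Bundle similarity views into a SimilarityViewSet
#'
#' @param entityKind `"miRNA"` or `"disease"`.
#' @param views Named list of square similarity matrices (standard names:
#'   `functional`, `sequence`, `gip` for miRNAs; `semantic`, `target`,
#'   `gip` for diseases). Any view may come from a file via
#'   [readSimilarityMatrix()] instead of being computed.
#' @param ids Entity identifiers; default taken from the first view.
#' @return A [SimilarityViewSet-class].
#' @export
similarityViewSet <- function(entityKind, views, ids = NULL) {
  if (is.null(ids)) {
    ids <- rownames(views[[1L]])
    if (is.null(ids)) ids <- sprintf("%s%03d", tolower(entityKind),
                                     seq_len(nrow(views[[1L]])))
  }
  views <- lapply(views, function(v) {
    v <- as.matrix(v)
    dimnames(v) <- list(ids, ids)
    v
  })
  new("SimilarityViewSet", entityKind = entityKind, views = views,
      ids = as.character(ids))
}
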