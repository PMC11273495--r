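#' @import methods
NULL

.checkPairMatrix <- function(p, km, kd, what) {
  if (!is.matrix(p) || ncol(p) != 2L || !is.numeric(p))
    return(sprintf("%s must be a two-column numeric matrix", what))
  if (nrow(p) > 0L) {
    if (any(p != floor(p))) return(sprintf("%s must hold integer indices", what))
    if (any(p[, 1L] < 1L) || any(p[, 1L] > km))
      return(sprintf("%s miRNA indices out of range", what))
    if (any(p[, 2L] < 1L) || any(p[, 2L] > kd))
      return(sprintf("%s disease indices out of range", what))
  }
  NULL
}

#' Bipartite miRNA-disease association dataset
#'
#' Holds the binary association matrix between an ordered miRNA universe and
#' an ordered disease universe, together with the labelled positive pairs
#' (known associations) and, once [sampleNegatives()] has been applied, an
#' equally sized set of sampled negative pairs.
#'
#' @slot miRNAs Ordered character vector of miRNA identifiers (length km).
#' @slot diseases Ordered character vector of disease identifiers (length kd).
#' @slot A Dense binary km x kd matrix; `A[i, j] == 1` iff miRNA i is a known
#'   associate of disease j.
#' @slot positivePairs Two-column integer matrix of (miRNA, disease) indices
#'   of the ones of `A`.
#' @slot negativePairs Two-column integer matrix of sampled zero cells;
#'   empty until negatives are drawn.
#'
#' @seealso [loadAssociations()], [sampleNegatives()], [makeSplits()]
#' @export
setClass("AssociationDataset",
  representation(
    miRNAs = "character",
    diseases = "character",
    A = "matrix",
    positivePairs = "matrix",
    negativePairs = "matrix"
  )
)

setValidity("AssociationDataset", function(object) {
  km <- length(object@miRNAs)
  kd <- length(object@diseases)
  A <- object@A
  if (!all(dim(A) == c(km, kd)))
    return("dim(A) must equal (length(miRNAs), length(diseases))")
  if (length(A) && !all(A %in% c(0, 1)))
    return("A must be binary")
  if (anyDuplicated(object@miRNAs)) return("duplicated miRNA identifiers")
  if (anyDuplicated(object@diseases)) return("duplicated disease identifiers")
  msg <- .checkPairMatrix(object@positivePairs, km, kd, "positivePairs")
  if (!is.null(msg)) return(msg)
  msg <- .checkPairMatrix(object@negativePairs, km, kd, "negativePairs")
  if (!is.null(msg)) return(msg)
  pos <- object@positivePairs
  if (sum(A == 1) != nrow(pos))
    return("positivePairs must enumerate exactly the ones of A")
  if (nrow(pos) && !all(A[pos] == 1))
    return("every positive pair must have A == 1")
  neg <- object@negativePairs
  if (nrow(neg) && !all(A[neg] == 0))
    return("every negative pair must have A == 0")
  TRUE
})

#' Train/test split with cross-validation folds
#'
#' Produced by [makeSplits()]. Pairs are stored as data frames with integer
#' columns `i` (miRNA index), `j` (disease index) and `label` (0/1); `folds`
#' holds disjoint index vectors into the rows of `train` that together
#' partition it.
#'
#' @slot train,test Labelled pair data frames (columns `i`, `j`, `label`).
#' @slot folds List of integer vectors partitioning `seq_len(nrow(train))`.
#' @slot seed Integer seed the split was drawn under.
#' @export
setClass("SplitSpec",
  representation(
    train = "data.frame",
    test = "data.frame",
    folds = "list",
    seed = "integer"
  )
)

setValidity("SplitSpec", function(object) {
  need <- c("i", "j", "label")
  for (nm in c("train", "test")) {
    df <- slot(object, nm)
    if (!all(need %in% names(df)))
      return(sprintf("%s must have columns i, j, label", nm))
    if (nrow(df) && !all(df$label %in% c(0, 1)))
      return(sprintf("%s labels must be 0/1", nm))
  }
  idx <- sort(unlist(object@folds, use.names = FALSE))
  if (length(object@folds)) {
    if (any(duplicated(idx))) return("folds must be disjoint")
    if (!identical(as.integer(idx), seq_len(nrow(object@train))))
      return("folds must partition the training pairs")
  }
  both <- rbind(object@train[need[1:2]], object@test[need[1:2]])
  if (anyDuplicated(both)) return("train and test pairs must be disjoint")
  TRUE
})

#' A set of homogeneous similarity views for one entity type
#'
#' Bundles the three similarity adjacency matrices used per node type:
#' `functional`, `sequence` and `gip` for miRNAs; `semantic`, `target` and
#' `gip` for diseases. Every view is square, symmetric, unit-diagonal and
#' valued in \[0, 1\], and all views share the entity ordering in `ids`.
#'
#' @slot entityKind `"miRNA"` or `"disease"`.
#' @slot views Named list of square numeric matrices.
#' @slot ids Ordered character vector of entity identifiers.
#' @export
setClass("SimilarityViewSet",
  representation(
    entityKind = "character",
    views = "list",
    ids = "character"
  )
)

setValidity("SimilarityViewSet", function(object) {
  if (!object@entityKind %in% c("miRNA", "disease"))
    return("entityKind must be 'miRNA' or 'disease'")
  n <- length(object@ids)
  if (!length(object@views)) return("at least one view required")
  if (is.null(names(object@views)) || any(!nzchar(names(object@views))))
    return("views must be named")
  for (nm in names(object@views)) {
    v <- object@views[[nm]]
    if (!is.matrix(v) || !all(dim(v) == c(n, n)))
      return(sprintf("view '%s' must be %d x %d", nm, n, n))
    if (max(abs(v - t(v))) > 1e-8)
      return(sprintf("view '%s' must be symmetric", nm))
    if (min(v) < -1e-10 || max(v) > 1 + 1e-10)
      return(sprintf("view '%s' must lie in [0, 1]", nm))
    if (max(abs(diag(v) - 1)) > 1e-10)
      return(sprintf("view '%s' must have a unit diagonal", nm))
  }
  TRUE
})

#' A similarity network after random-walk association masking
#'
#' Result of [applyAssociationMask()]: the masked adjacency, the record of
#' entries it changed, the random-walk paths whose coverage defined the mask
#' and the Bernoulli-sampled start nodes.
#'
#' @slot Amask Square numeric matrix after masking.
#' @slot maskedEntries Two-column integer matrix of entries changed from
#'   nonzero to zero.
#' @slot paths Named list mapping start node to its walk (integer sequence).
#' @slot startNodes Integer vector of sampled start nodes.
#' @export
setClass("MaskedGraph",
  representation(
    Amask = "matrix",
    maskedEntries = "matrix",
    paths = "list",
    startNodes = "integer"
  )
)

setValidity("MaskedGraph", function(object) {
  n <- nrow(object@Amask)
  if (ncol(object@Amask) != n) return("Amask must be square")
  me <- object@maskedEntries
  if (!is.matrix(me) || ncol(me) != 2L)
    return("maskedEntries must be a two-column matrix")
  if (nrow(me) && (min(me) < 1L || max(me) > n))
    return("maskedEntries indices out of range")
  if (nrow(me) && any(object@Amask[me] != 0))
    return("masked entries must be zero in Amask")
  TRUE
})

#' Supernode heterogeneous hypergraph bundle
#'
#' The assembled miRNA-disease-supernode graph: node embeddings, the
#' cosine coupling weights of each entity to every supernode, and the
#' combined `(km + kd + q)^2` adjacency whose miRNA-disease block holds the
#' training positives only.
#'
#' @slot Xm,Xd,Q Embedding matrices (km x E, kd x E, q x E).
#' @slot Cmq,Cdq Cosine weight matrices (km x q, kd x q), in \[-1, 1\].
#' @slot Ahyper Symmetric assembled adjacency over km + kd + q nodes.
#' @export
setClass("HypergraphBundle",
  representation(
    Xm = "matrix", Xd = "matrix", Q = "matrix",
    Cmq = "matrix", Cdq = "matrix", Ahyper = "matrix"
  )
)

setValidity("HypergraphBundle", function(object) {
  km <- nrow(object@Xm); kd <- nrow(object@Xd); q <- nrow(object@Q)
  if (length(unique(c(ncol(object@Xm), ncol(object@Xd), ncol(object@Q)))) != 1L)
    return("embedding dimensions must agree")
  if (!all(dim(object@Cmq) == c(km, q)) || !all(dim(object@Cdq) == c(kd, q)))
    return("cosine weight matrices have wrong shape")
  if (min(object@Cmq) < -1 - 1e-8 || max(object@Cmq) > 1 + 1e-8 ||
      min(object@Cdq) < -1 - 1e-8 || max(object@Cdq) > 1 + 1e-8)
    return("cosine weights must lie in [-1, 1]")
  n <- km + kd + q
  if (!all(dim(object@Ahyper) == c(n, n)))
    return("Ahyper must be (km + kd + q) square")
  if (max(abs(object@Ahyper - t(object@Ahyper))) > 1e-8)
    return("Ahyper must be symmetric")
  if (any(object@Ahyper[seq_len(km), seq_len(km)] != 0) ||
      any(object@Ahyper[km + seq_len(kd), km + seq_len(kd)] != 0))
    return("within-type blocks must be empty (cross-talk goes via supernodes)")
  TRUE
})

#' Full model configuration
#'
#' Groups every tunable of the pipeline. Defaults (see [modelConfig()])
#' reproduce the published operating point: 4 attention heads, 2 GCN layers,
#' maximum path length 8, feed-forward width 2048, mask ratio 0.3, restart
#' probability 0.6, 64 supernodes, dropout 0.5 and DCE weight alpha = 0.8.
#'
#' @slot mask List: `p`, `c`, `k`, `mode`, `resample`.
#' @slot homo List: `dim`, `layers`, `dropout`.
#' @slot gct List: `heads`, `layers`, `ffnHidden`, `maxSp`, `supernodes`,
#'   `biasMode`, `dropout`.
#' @slot loss List: `alpha`, `smoothEps`.
#' @slot head List: `convKernel`.
#' @slot optim List: `lr`, `epochs`, `weightDecay`.
#' @slot ablation One of `"full"`, `"HGT-A"`, `"HGT-B"`, `"HGT-C"`, `"HGT-D"`.
#' @slot seed Integer global seed.
#' @export
setClass("ModelConfig",
  representation(
    mask = "list",
    homo = "list",
    gct = "list",
    loss = "list",
    head = "list",
    optim = "list",
    ablation = "character",
    seed = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  m <- object@mask
  if (m$p < 0 || m$p > 1) return("mask$p must lie in [0, 1]")
  if (m$c < 0 || m$c > 1) return("mask$c must lie in [0, 1]")
  if (m$k < 0) return("mask$k must be >= 0")
  if (!m$mode %in% c("complement", "literal"))
    return("mask$mode must be 'complement' or 'literal'")
  g <- object@gct
  if (object@homo$dim %% g$heads != 0)
    return("attention heads must divide the embedding dimension")
  if (any(unlist(g[c("heads", "layers", "ffnHidden", "maxSp", "supernodes")]) < 1))
    return("gct settings must be positive")
  if (!g$biasMode %in% c("embedding", "raw"))
    return("gct$biasMode must be 'embedding' or 'raw'")
  a <- object@loss$alpha
  if (a < 0 || a > 1) return("loss$alpha must lie in [0, 1]")
  if (!object@ablation %in% c("full", "HGT-A", "HGT-B", "HGT-C", "HGT-D"))
    return("unknown ablation variant")
  TRUE
})

#' Cross-validation / test evaluation report
#'
#' @slot perFold Data frame with one row per fold (or a single row for a
#'   plain train/test evaluation) and columns `fold`, `acc`, `f1`, `recall`,
#'   `precision`, `auc`, `auprc`.
#' @slot means Named numeric vector of column means over folds.
#' @slot ranked List of per-disease ranked score tables (possibly empty).
#' @export
setClass("EvalReport",
  representation(
    perFold = "data.frame",
    means = "numeric",
    ranked = "list"
  )
)

setValidity("EvalReport", function(object) {
  metr <- c("acc", "f1", "recall", "precision", "auc", "auprc")
  if (!all(metr %in% names(object@perFold)))
    return("perFold must carry acc, f1, recall, precision, auc, auprc")
  vals <- unlist(object@perFold[metr])
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    return("metrics must lie in [0, 1]")
  TRUE
})
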