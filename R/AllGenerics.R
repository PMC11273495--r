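#' Accessors for the core classes
#'
#' Small accessor family: identifier vectors, the association matrix, the
#' labelled pair sets, similarity views and mask records are read through
#' these rather than via `@`.
#'
#' @param x An object of the documented class.
#' @param name For [getView()], the view name (e.g. `"gip"`).
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("miRNAIds", function(x) standardGeneric("miRNAIds"))
#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))
#' @rdname accessors
#' @export
setGeneric("associationMatrix", function(x) standardGeneric("associationMatrix"))
#' @rdname accessors
#' @export
setGeneric("positivePairs", function(x) standardGeneric("positivePairs"))
#' @rdname accessors
#' @export
setGeneric("negativePairs", function(x) standardGeneric("negativePairs"))
#' @rdname accessors
#' @export
setGeneric("viewNames", function(x) standardGeneric("viewNames"))
#' @rdname accessors
#' @export
setGeneric("getView", function(x, name) standardGeneric("getView"))
#' @rdname accessors
#' @export
setGeneric("maskedAdjacency", function(x) standardGeneric("maskedAdjacency"))
#' @rdname accessors
#' @export
setGeneric("maskedEntries", function(x) standardGeneric("maskedEntries"))

#' @rdname accessors
#' @export
setMethod("miRNAIds", "AssociationDataset", function(x) x@miRNAs)
#' @rdname accessors
#' @export
setMethod("diseaseIds", "AssociationDataset", function(x) x@diseases)
#' @rdname accessors
#' @export
setMethod("associationMatrix", "AssociationDataset", function(x) x@A)
#' @rdname accessors
#' @export
setMethod("positivePairs", "AssociationDataset", function(x) x@positivePairs)
#' @rdname accessors
#' @export
setMethod("negativePairs", "AssociationDataset", function(x) x@negativePairs)

#' @rdname accessors
#' @export
setMethod("viewNames", "SimilarityViewSet", function(x) names(x@views))
#' @rdname accessors
#' @export
setMethod("getView", "SimilarityViewSet", function(x, name) {
  if (!name %in% names(x@views))
    stop("no view named '", name, "'; available: ",
         paste(names(x@views), collapse = ", "))
  x@views[[name]]
})

#' @rdname accessors
#' @export
setMethod("maskedAdjacency", "MaskedGraph", function(x) x@Amask)
#' @rdname accessors
#' @export
setMethod("maskedEntries", "MaskedGraph", function(x) x@maskedEntries)

setMethod("show", "AssociationDataset", function(object) {
  cat(sprintf(
    "AssociationDataset: %d miRNAs x %d diseases\n  %d positive pairs, %d negative pairs (density %.3f)\n",
    length(object@miRNAs), length(object@diseases),
    nrow(object@positivePairs), nrow(object@negativePairs),
    mean(object@A)
  ))
})

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf(
    "SplitSpec: %d train / %d test pairs, %d folds (seed %d)\n",
    nrow(object@train), nrow(object@test), length(object@folds), object@seed
  ))
})

setMethod("show", "SimilarityViewSet", function(object) {
  cat(sprintf(
    "SimilarityViewSet (%s): %d entities, views: %s\n",
    object@entityKind, length(object@ids),
    paste(names(object@views), collapse = ", ")
  ))
})

setMethod("show", "MaskedGraph", function(object) {
  cat(sprintf(
    "MaskedGraph: %d nodes, %d start nodes, %d entries masked\n",
    nrow(object@Amask), length(object@startNodes), nrow(object@maskedEntries)
  ))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig (%s): dim %d, heads %d, gct layers %d, ffn %d, supernodes %d\n  mask p=%.2f c=%.2f k=%d mode=%s | alpha=%.2f | lr=%g epochs=%d | seed %d\n",
    object@ablation, object@homo$dim, object@gct$heads, object@gct$layers,
    object@gct$ffnHidden, object@gct$supernodes,
    object@mask$p, object@mask$c, object@mask$k, object@mask$mode,
    object@loss$alpha, object@optim$lr, object@optim$epochs, object@seed
  ))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport over", nrow(object@perFold), "fold(s):\n")
  print(round(object@means, 4))
})
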