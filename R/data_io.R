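#' Construct an association dataset from a binary matrix
#'
#' @param A Binary miRNA x disease matrix (rows = miRNAs).
#' @param miRNAs,diseases Identifier vectors; default to the dimnames of `A`
#'   or generated labels.
#' @return An [AssociationDataset-class].
#' @examples
#' A <- matrix(c(1, 1, 0, 1), 2, 2)
#' associationDataset(A)
#' @export
associationDataset <- function(A, miRNAs = rownames(A), diseases = colnames(A)) {
  if (!is.matrix(A)) A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (is.null(miRNAs)) miRNAs <- sprintf("mirna%03d", seq_len(nrow(A)))
  if (is.null(diseases)) diseases <- sprintf("disease%03d", seq_len(ncol(A)))
  dimnames(A) <- list(miRNAs, diseases)
  pos <- which(A == 1, arr.ind = TRUE)
  new("AssociationDataset",
    miRNAs = as.character(miRNAs), diseases = as.character(diseases),
    A = A, positivePairs = .pairMatrix(pos[, 1], pos[, 2]),
    negativePairs = .emptyPairs()
  )
}

.headerLabels <- c(
  "mirna", "mirnas", "mir", "microrna", "mi-rna",
  "disease", "diseases", "dis", "phenotype"
)

#' Read a miRNA-disease edge list
#'
#' Reads a two-or-more column TSV/CSV of (miRNA id, disease id) pairs into an
#' [AssociationDataset-class]. Identifiers are trimmed and matched
#' case-insensitively; duplicated pairs collapse to a single association. The
#' field separator is taken from the first line (tab if present, else comma)
#' unless given, and a header row is recognised when its first two fields are
#' conventional column labels such as `miRNA` / `disease`.
#'
#' @param path Path to the edge-list file.
#' @param miRNAUniverse,diseaseUniverse Optional identifier universes fixing
#'   the row/column order; default to the sorted distinct ids observed.
#' @param sep Field separator; `NULL` to auto-detect.
#' @param header `"auto"`, `TRUE` or `FALSE`.
#' @return An [AssociationDataset-class].
#' @export
loadAssociations <- function(path, miRNAUniverse = NULL, diseaseUniverse = NULL,
                             sep = NULL, header = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty association file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s (need >= 2 columns)",
                 bad[[1L]], path))
  first <- .normalizeId(fields[[1L]][1:2])
  hasHeader <- if (identical(header, "auto"))
    all(first %in% .headerLabels) else isTRUE(header)
  if (hasHeader) fields <- fields[-1L]
  if (!length(fields)) stop("no association rows in ", path)
  mir <- .normalizeId(vapply(fields, `[[`, "", 1L))
  dis <- .normalizeId(vapply(fields, `[[`, "", 2L))
  if (any(!nzchar(mir)) || any(!nzchar(dis)))
    stop(sprintf("empty identifier at line %d of %s",
                 which(!nzchar(mir) | !nzchar(dis))[[1L]] + hasHeader, path))
  keep <- !duplicated(paste(mir, dis, sep = "\r"))
  mir <- mir[keep]; dis <- dis[keep]
  miRNAs <- if (is.null(miRNAUniverse)) sort(unique(mir))
    else .normalizeId(miRNAUniverse)
  diseases <- if (is.null(diseaseUniverse)) sort(unique(dis))
    else .normalizeId(diseaseUniverse)
  mi <- match(mir, miRNAs); di <- match(dis, diseases)
  if (anyNA(mi)) stop("miRNA id outside the given universe: ", mir[is.na(mi)][1L])
  if (anyNA(di)) stop("disease id outside the given universe: ", dis[is.na(di)][1L])
  A <- matrix(0, length(miRNAs), length(diseases),
              dimnames = list(miRNAs, diseases))
  A[cbind(mi, di)] <- 1
  associationDataset(A, miRNAs, diseases)
}

#' Write the canonical edge list of a dataset
#'
#' Writes the known associations as a sorted, deduplicated two-column TSV
#' with a `miRNA`/`disease` header, the canonical on-disk form that
#' [loadAssociations()] round-trips.
#'
#' @param ds An [AssociationDataset-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAssociations <- function(ds, path) {
  stopifnot(is(ds, "AssociationDataset"))
  p <- positivePairs(ds)
  df <- data.frame(
    miRNA = miRNAIds(ds)[p[, 1L]],
    disease = diseaseIds(ds)[p[, 2L]],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$miRNA, df$disease), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Draw balanced negative pairs
#'
#' Samples, uniformly at random among the zero cells of the association
#' matrix, exactly as many negative pairs as there are known associations,
#' yielding the balanced labelled dataset the model trains on. All zero
#' cells are treated alike (unverified non-associations are
#' indistinguishable from merely unobserved pairs).
#'
#' @param ds An [AssociationDataset-class].
#' @param seed Integer seed; identical seeds give identical draws.
#' @return The dataset with `negativePairs` filled in.
#' @export
sampleNegatives <- function(ds, seed = 1L) {
  stopifnot(is(ds, "AssociationDataset"))
  A <- associationMatrix(ds)
  zeros <- which(A == 0)
  nPos <- nrow(positivePairs(ds))
  if (length(zeros) < nPos)
    stop(sprintf("cannot draw %d negatives from %d zero cells",
                 nPos, length(zeros)))
  picked <- .withSeed(seed, sample(zeros, nPos))
  idx <- arrayInd(picked, dim(A))
  ds@negativePairs <- .pairMatrix(idx[, 1L], idx[, 2L])
  validObject(ds)
  ds
}

.labelledPairs <- function(ds) {
  pos <- positivePairs(ds); neg <- negativePairs(ds)
  data.frame(
    i = c(pos[, 1L], neg[, 1L]),
    j = c(pos[, 2L], neg[, 2L]),
    label = rep(c(1L, 0L), c(nrow(pos), nrow(neg)))
  )
}

#' Build a stratified train/test split with cross-validation folds
#'
#' Splits the labelled pairs (positives plus sampled negatives) into a
#' training set and an independent test set, then partitions the training
#' pairs into `kFolds` disjoint validation folds. Both the split and the
#' folds are stratified by label so the 1:1 positive:negative balance holds
#' in every partition.
#'
#' @param ds An [AssociationDataset-class] with negatives sampled.
#' @param testFraction Fraction of pairs held out for testing (default 0.2,
#'   i.e. an 8:2 split). `0` keeps every pair in the training partition,
#'   the cross-validation-on-all-data protocol.
#' @param kFolds Number of cross-validation folds (default 5).
#' @param seed Integer seed; identical inputs and seed give an identical
#'   split.
#' @return A [SplitSpec-class].
#' @export
makeSplits <- function(ds, testFraction = 0.2, kFolds = 5L, seed = 1L) {
  stopifnot(is(ds, "AssociationDataset"))
  if (testFraction < 0 || testFraction >= 1)
    stop("testFraction must lie in [0, 1)")
  if (kFolds < 2L) stop("kFolds must be >= 2")
  pairs <- .labelledPairs(ds)
  if (!nrow(pairs)) stop("dataset has no labelled pairs")
  .withSeed(seed, {
    testIdx <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$label), function(g) {
      sample(g, round(length(g) * testFraction))
    }), use.names = FALSE)
    train <- if (length(testIdx)) pairs[-testIdx, , drop = FALSE] else pairs
    test <- pairs[testIdx, , drop = FALSE]
    if (nrow(train) < kFolds)
      stop(sprintf("%d training pairs cannot fill %d folds", nrow(train), kFolds))
    foldOf <- integer(nrow(train))
    for (g in split(seq_len(nrow(train)), train$label))
      foldOf[sample(g)] <- rep_len(seq_len(kFolds), length(g))
    rownames(train) <- rownames(test) <- NULL
    new("SplitSpec",
      train = train, test = test,
      folds = unname(split(seq_len(nrow(train)), foldOf)),
      seed = as.integer(seed)
    )
  })
}

#' Read / write a square similarity matrix as TSV
#'
#' Dense similarity matrices travel as tab-separated text with a header row
#' of identifiers and an identifier index column, so files stay
#' human-inspectable and diffable.
#'
#' @param path File path.
#' @param M Square numeric matrix with identifier dimnames.
#' @return `readSimilarityMatrix` returns the matrix; `writeSimilarityMatrix`
#'   returns `path` invisibly.
#' @export
readSimilarityMatrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  M <- as.matrix(df)
  .assertSquare(M, paste0("matrix in ", path))
  M
}

#' @rdname readSimilarityMatrix
#' @export
writeSimilarityMatrix <- function(M, path) {
  .assertSquare(M)
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
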