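#' Specification of the synthetic benchmark
#'
#' Desk-scale generator emulating the statistical shape the model assumes:
#' a bipartite association matrix with planted low-rank structure (the
#' association literature models the miRNA-disease matrix as approximately
#' low rank) plus three noisy-but-consistent similarity views per entity
#' type, so the attention fusion and masking stages see redundant signal.
#'
#' @param km,kd Entity counts (default 100 miRNAs, 60 diseases).
#' @param rank Latent factor count (default 5).
#' @param noiseFlipRate Probability of flipping each association cell
#'   (default 0.05).
#' @param simNoiseSd Additive noise on the latent factors before each
#'   similarity view is formed (default 0.1).
#' @param quantile Score quantile above which a cell becomes a positive
#'   (default 0.8, i.e. ~20% density before flips).
#' @param seed Integer seed.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(km = 100L, kd = 60L, rank = 5L,
                          noiseFlipRate = 0.05, simNoiseSd = 0.1,
                          quantile = 0.8, seed = 7L) {
  if (rank >= min(km, kd)) stop("rank must be < min(km, kd)")
  if (noiseFlipRate < 0 || noiseFlipRate >= 1) stop("noiseFlipRate in [0, 1)")
  if (simNoiseSd < 0) stop("simNoiseSd must be >= 0")
  structure(list(km = as.integer(km), kd = as.integer(kd),
                 rank = as.integer(rank), noiseFlipRate = noiseFlipRate,
                 simNoiseSd = simNoiseSd, quantile = quantile,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# Cosine similarity between the rows of a factor matrix, clipped to [0, 1]
# with a unit diagonal (a valid similarity view).
.cosineView <- function(U) {
  n <- sqrt(rowSums(U^2))
  n[n == 0] <- 1
  S <- tcrossprod(U / n)
  S <- (S + t(S)) / 2
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  S
}

#' Generate a synthetic association benchmark
#'
#' Draws nonnegative latent factors `U` (km x rank) and `V` (kd x rank),
#' plants associations where `U V^T` exceeds the configured score quantile,
#' then flips cells at the noise rate. Each entity type gets three
#' similarity views: cosine similarities of the latent factors under three
#' independent noise draws, so the views carry redundant but non-identical
#' signal (with zero noise they are identical). Ground-truth factors are
#' returned for recovery checks.
#'
#' @param spec A [syntheticSpec()].
#' @return List with `ds` (an [AssociationDataset-class]),
#'   `mirnaViews` and `diseaseViews` ([SimilarityViewSet-class]),
#'   and `factors` (list `U`, `V`, `scores`).
#' @export
generateSynthetic <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .withSeed(spec$seed, {
    U <- matrix(abs(stats::rnorm(spec$km * spec$rank)), spec$km, spec$rank)
    V <- matrix(abs(stats::rnorm(spec$kd * spec$rank)), spec$kd, spec$rank)
    scores <- tcrossprod(U, V)
    A <- (scores > stats::quantile(scores, spec$quantile)) * 1
    if (spec$noiseFlipRate > 0) {
      flip <- matrix(stats::runif(length(A)) < spec$noiseFlipRate,
                     nrow(A), ncol(A))
      A <- abs(A - flip)
    }
    if (all(A == 0))
      stop("degenerate all-zero association matrix; lower the quantile")
    ds <- associationDataset(
      A,
      miRNAs = sprintf("mirna%03d", seq_len(spec$km)),
      diseases = sprintf("disease%03d", seq_len(spec$kd))
    )
    noisyView <- function(W) {
      .cosineView(W + matrix(stats::rnorm(length(W), sd = spec$simNoiseSd),
                             nrow(W), ncol(W)))
    }
    mv <- similarityViewSet("miRNA",
      list(functional = noisyView(U), sequence = noisyView(U),
           gip = noisyView(U)), ids = miRNAIds(ds))
    dv <- similarityViewSet("disease",
      list(semantic = noisyView(V), target = noisyView(V),
           gip = noisyView(V)), ids = diseaseIds(ds))
    list(ds = ds, mirnaViews = mv, diseaseViews = dv,
         factors = list(U = U, V = V, scores = scores))
  })
}

#' Write a synthetic benchmark to disk
#'
#' Writes the standard text artefacts consumed by the loaders: the
#' association edge list and one TSV per similarity view.
#'
#' @param sim Output of [generateSynthetic()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSynthetic <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeAssociations(sim$ds, file.path(dir, "associations.tsv"))
  for (nm in viewNames(sim$mirnaViews))
    writeSimilarityMatrix(getView(sim$mirnaViews, nm),
                          file.path(dir, sprintf("mirna_%s.tsv", nm)))
  for (nm in viewNames(sim$diseaseViews))
    writeSimilarityMatrix(getView(sim$diseaseViews, nm),
                          file.path(dir, sprintf("disease_%s.tsv", nm)))
  invisible(dir)
}
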