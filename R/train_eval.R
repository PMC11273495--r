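#' Build a model configuration
#'
#' Defaults reproduce the published operating point: mask ratio 0.3,
#' restart probability 0.6, maximum path length 8, embedding width 128,
#' 2 GCN layers, 4 attention heads, feed-forward width 2048, 64 supernodes,
#' dropout 0.5 and DCE weight 0.8. Ablation variants are selected purely by
#' configuration: `"HGT-A"` removes association masking, `"HGT-B"` masks
#' without restarts (c = 0), `"HGT-C"` replaces the GCN-Transformer
#' encoder with a plain GCN, `"HGT-D"` replaces the DCE loss with standard
#' binary cross-entropy.
#'
#' @param dim Embedding width E (must be divisible by `heads`).
#' @param maskP,maskC,maskK,maskMode,resampleMask Masking strategy: start
#'   sampling rate, restart probability, path length, `"complement"` or
#'   `"literal"`, and whether masks are resampled each epoch.
#' @param homoLayers,homoDropout Homogeneous GCN depth and dropout.
#' @param homoFeatures Initial node features for the homogeneous encoders:
#'   `"profile"` (default) feeds each node its mean similarity profile
#'   through the learned projection, so the view geometry enters the
#'   encoder directly; `"onehot"` uses identity-like one-hot rows, making
#'   the projection a free per-node embedding.
#' @param heads,gctLayers,ffnHidden,maxSp,supernodes,biasMode,gctDropout
#'   GCN-Transformer settings.
#' @param alpha,smoothEps DCE mixing weight and Dice smoothing.
#' @param lr,epochs,weightDecay Adam optimiser settings.
#' @param batchFraction Fraction of the training pairs scored in each
#'   epoch's loss (default 1 = full batch); smaller values inject
#'   minibatch-style gradient noise.
#' @param lrSchedule `"constant"` or `"cosine"` (decay to 10% of `lr` over
#'   the run).
#' @param emaDecay Exponential-moving-average decay for the inference
#'   weights (0 disables averaging). Weight averaging smooths the gradient
#'   noise injected by per-epoch mask resampling; the raw final weights are
#'   kept for the loss trajectory either way.
#' @param ablation `"full"` or one of `"HGT-A"`..`"HGT-D"`.
#' @param seed Global seed for initialisation, masking and dropout.
#' @return A [ModelConfig-class].
#' @export
modelConfig <- function(dim = 128L, maskP = 0.3, maskC = 0.6, maskK = 8L,
                        maskMode = "complement", resampleMask = TRUE,
                        homoLayers = 2L, homoDropout = 0.5,
                        homoFeatures = "onehot",
                        heads = 4L, gctLayers = 2L, ffnHidden = 2048L,
                        maxSp = 8L, supernodes = 64L,
                        biasMode = "embedding", gctDropout = 0.5,
                        alpha = 0.8, smoothEps = 0,
                        lr = 1e-3, epochs = 200L, weightDecay = 0,
                        batchFraction = 1,
                        lrSchedule = "constant", emaDecay = 0,
                        ablation = "full", seed = 1L) {
  new("ModelConfig",
    mask = list(p = maskP, c = maskC, k = as.integer(maskK),
                mode = maskMode, resample = isTRUE(resampleMask)),
    homo = list(dim = as.integer(dim), layers = as.integer(homoLayers),
                dropout = homoDropout, features = homoFeatures),
    gct = list(heads = as.integer(heads), layers = as.integer(gctLayers),
               ffnHidden = as.integer(ffnHidden), maxSp = as.integer(maxSp),
               supernodes = as.integer(supernodes), biasMode = biasMode,
               dropout = gctDropout),
    loss = list(alpha = alpha, smoothEps = smoothEps),
    head = list(convKernel = 3L),
    optim = list(lr = lr, epochs = as.integer(epochs),
                 weightDecay = weightDecay, batchFraction = batchFraction,
                 lrSchedule = lrSchedule, emaDecay = emaDecay),
    ablation = ablation,
    seed = as.integer(seed)
  )
}

.glorot <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)

# All trainable weights as one flat named list of matrices (draws from the
# current RNG stream; callers seed it).
.initParams <- function(km, kd, cfg) {
  E <- cfg@homo$dim
  P <- list(
    X0_m = matrix(stats::rnorm(km * E, sd = 0.1), km, E),
    X0_d = matrix(stats::rnorm(kd * E, sd = 0.1), kd, E),
    attn_m = matrix(stats::rnorm(E, sd = sqrt(1 / E)), E, 1L),
    attn_d = matrix(stats::rnorm(E, sd = sqrt(1 / E)), E, 1L),
    Q = matrix(stats::rnorm(cfg@gct$supernodes * E, sd = 0.1),
               cfg@gct$supernodes, E)
  )
  for (e in c("m", "d")) for (v in 1:3) for (l in seq_len(cfg@homo$layers))
    P[[sprintf("homo.%s.v%d.W%d", e, v, l)]] <- .glorot(E, E)
  for (l in seq_len(cfg@gct$layers)) {
    lp <- initGctLayerParams(E, cfg@gct$ffnHidden)
    names(lp) <- sprintf("gct%d.%s", l, names(lp))
    P <- c(P, lp)
  }
  P$spbias <- matrix(-0.3 * (0:cfg@gct$maxSp), 1L)  # nearer nodes start larger
  P$fuse_m <- matrix(0, 1L, 2L)
  P$fuse_d <- matrix(0, 1L, 2L)
  c(P, initHeadParams(E))
}

.layerParams <- function(P, l) {
  nms <- c("Wg", "Wq", "Wk", "Wv", "WO", "F1", "b1", "F2", "b2",
           "ln1g", "ln1b", "ln2g", "ln2b")
  stats::setNames(P[sprintf("gct%d.%s", l, nms)], nms)
}

.headParams <- function(P) P[c("conv_w", "conv_b", "head_w", "head_b")]

# Per-epoch masked + normalised similarity views (uses the current RNG
# stream). HGT-A skips masking entirely; HGT-B masks with c = 0.
.maskedViewInputs <- function(views, cfg) {
  m <- cfg@mask
  cUse <- if (cfg@ablation == "HGT-B") 0 else m$c
  lapply(views, function(A) {
    if (cfg@ablation == "HGT-A") return(gcnNormalize(A))
    gcnNormalize(maskedAdjacency(
      maskSimilarityView(A, p = m$p, c = cUse, k = m$k, mode = m$mode)))
  })
}

# Full pipeline forward pass. `P` is the flat parameter list, numeric for
# inference or tape nodes for training; `inp` carries the normalised view
# adjacencies, training positives, forbidden pairs and pairs to score.
.modelForward <- function(P, inp, cfg, training = FALSE) {
  layers <- seq_len(cfg@homo$layers)
  encodeEntity <- function(hatViews, X0, feat, wPrefix, score) {
    if (!is.null(feat)) X0 <- adMM(feat, X0)
    per <- lapply(seq_along(hatViews), function(v) {
      W <- P[sprintf("%s.v%d.W%d", wPrefix, v, layers)]
      .gcnForward(hatViews[[v]], X0, W,
                  dropout = cfg@homo$dropout, training = training)
    })
    .attentionFuse(per, score)$fused
  }
  Xm <- encodeEntity(inp$AmHat, P$X0_m, inp$Fm, "homo.m", P$attn_m)
  Xd <- encodeEntity(inp$AdHat, P$X0_d, inp$Fd, "homo.d", P$attn_d)
  km <- nrow(adValue(Xm)); kd <- nrow(adValue(Xd))
  # Hypergraph adjacency built on detached values; gradients reach the
  # encoders and Q through the node features, not the adjacency. A caller
  # may inject a fixed adjacency (inp$Ahyper) instead.
  bundle <- NULL
  Ahyper <- inp$Ahyper
  if (is.null(Ahyper)) {
    bundle <- assembleHypergraph(adValue(Xm), adValue(Xd), adValue(P$Q),
                                 knownPairs = inp$trainPos,
                                 forbiddenPairs = inp$forbidden)
    Ahyper <- bundle@Ahyper
  }
  Ahat <- gcnNormalize(Ahyper)
  Dsp <- shortestPathMatrix(Ahyper, maxSp = cfg@gct$maxSp)
  bias <- if (cfg@gct$biasMode == "raw")
    matrix(as.numeric(Dsp), nrow(Dsp), ncol(Dsp))
  else adGatherBias(P$spbias, Dsp)
  H <- adRbind(list(Xm, Xd, P$Q))
  for (l in seq_len(cfg@gct$layers))
    H <- .gctLayerForward(H, Ahat, bias, .layerParams(P, l),
                          heads = cfg@gct$heads, dropout = cfg@gct$dropout,
                          training = training,
                          plainGcn = cfg@ablation == "HGT-C")
  Zm <- adRows(H, seq_len(km))
  Zd <- adRows(H, km + seq_len(kd))
  mFull <- .fuseRepresentations(Xm, Zm, P$fuse_m)
  dFull <- .fuseRepresentations(Xd, Zd, P$fuse_d)
  scores <- NULL
  if (!is.null(inp$scorePairs) && nrow(inp$scorePairs)) {
    scores <- .scoreForward(adRows(mFull, inp$scorePairs[, 1L]),
                            adRows(dFull, inp$scorePairs[, 2L]),
                            .headParams(P))
  }
  list(scores = scores, embM = mFull, embD = dFull, bundle = bundle)
}

.adamStep <- function(P, grads, state, lr, wd, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (wd > 0) g <- g + wd * P[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mh <- state$m[[nm]] / (1 - b1^t)
    vh <- state$v[[nm]] / (1 - b2^t)
    P[[nm]] <- P[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  P
}

.viewList <- function(x) {
  if (is(x, "SimilarityViewSet")) x@views
  else if (is.list(x)) x
  else list(x)
}

#' Train the full association model
#'
#' Runs the end-to-end loop: per epoch, the similarity views are re-masked
#' by restart random walks (unless `resampleMask` is off or the ablation
#' removes masking), both entity types are encoded by the attention-fused
#' GCNs, the supernode hypergraph is assembled from the *training*
#' positives only, the GCN-Transformer encodes the joint graph, the
#' training pairs are scored, and one Adam step is taken on the DCE loss
#' (plain cross-entropy for the HGT-D variant). Fully reproducible under
#' the configuration seed.
#'
#' @param ds An [AssociationDataset-class] (for identifiers and, by
#'   default, the labelled pairs).
#' @param mirnaViews,diseaseViews [SimilarityViewSet-class] objects (or
#'   plain lists of matrices).
#' @param cfg A [ModelConfig-class].
#' @param trainPairs Data frame (`i`, `j`, `label`) of training pairs;
#'   defaults to all labelled pairs of `ds`.
#' @param forbiddenPairs Optional two-column matrix of held-out pairs; the
#'   hypergraph assembly errors if any of them leaks into its edges.
#' @param verbose Print the loss every 10 epochs.
#' @return An object of class `HgtModel`: trained weights, the loss
#'   trajectory, final-state embeddings and bookkeeping for prediction.
#' @export
trainModel <- function(ds, mirnaViews, diseaseViews, cfg = modelConfig(),
                       trainPairs = NULL, forbiddenPairs = NULL,
                       verbose = FALSE) {
  stopifnot(is(ds, "AssociationDataset"), is(cfg, "ModelConfig"))
  mv <- .viewList(mirnaViews); dv <- .viewList(diseaseViews)
  km <- length(miRNAIds(ds)); kd <- length(diseaseIds(ds))
  if (any(vapply(mv, nrow, 1L) != km)) stop("miRNA views must be km x km")
  if (any(vapply(dv, nrow, 1L) != kd)) stop("disease views must be kd x kd")
  if (is.null(trainPairs)) trainPairs <- .labelledPairs(ds)
  trainPos <- as.matrix(trainPairs[trainPairs$label == 1, c("i", "j")])
  y <- trainPairs$label
  scoreIdx <- as.matrix(trainPairs[, c("i", "j")])
  alpha <- if (cfg@ablation == "HGT-D") 0 else cfg@loss$alpha
  # Similarity-profile feature bases (column-centred so the uninformative
  # global similarity level drops out); NULL selects one-hot features.
  profileBasis <- function(views) {
    S <- Reduce(`+`, views) / length(views)
    sweep(S, 2L, colMeans(S))
  }
  Fm <- if (identical(cfg@homo$features, "profile")) profileBasis(mv) else NULL
  Fd <- if (identical(cfg@homo$features, "profile")) profileBasis(dv) else NULL
  .withSeed(cfg@seed, {
    P <- .initParams(km, kd, cfg)
    state <- new.env(parent = emptyenv())
    state$m <- lapply(P, function(x) x * 0)
    state$v <- lapply(P, function(x) x * 0)
    losses <- numeric(cfg@optim$epochs)
    Pema <- NULL
    fixedInp <- if (!cfg@mask$resample || cfg@ablation == "HGT-A")
      list(Am = .maskedViewInputs(mv, cfg), Ad = .maskedViewInputs(dv, cfg))
    else NULL
    bf <- cfg@optim$batchFraction
    for (epoch in seq_len(cfg@optim$epochs)) {
      batch <- if (bf < 1) sort(sample(length(y), ceiling(bf * length(y))))
               else seq_along(y)
      inp <- list(
        AmHat = if (is.null(fixedInp)) .maskedViewInputs(mv, cfg) else fixedInp$Am,
        AdHat = if (is.null(fixedInp)) .maskedViewInputs(dv, cfg) else fixedInp$Ad,
        trainPos = trainPos, forbidden = forbiddenPairs,
        scorePairs = scoreIdx[batch, , drop = FALSE], Fm = Fm, Fd = Fd
      )
      tape <- adTape()
      nodes <- lapply(P, function(x) adParam(tape, x))
      fwd <- .modelForward(nodes, inp, cfg, training = TRUE)
      loss <- .adDceLoss(fwd$scores, y[batch], alpha = alpha,
                         smooth = cfg@loss$smoothEps)
      lv <- as.numeric(adValue(loss))
      if (!is.finite(lv))
        stop(sprintf(
          "non-finite loss at epoch %d (last finite: %s); try a lower learning rate",
          epoch, if (epoch > 1) format(losses[epoch - 1]) else "none"))
      adBackward(loss)
      grads <- lapply(nodes, function(nd) nd$grad)
      lrE <- if (identical(cfg@optim$lrSchedule, "cosine"))
        cfg@optim$lr * (0.55 + 0.45 * cos(pi * (epoch - 1) / cfg@optim$epochs))
      else cfg@optim$lr
      P <- .adamStep(P, grads, state, lrE, cfg@optim$weightDecay, epoch)
      ed <- cfg@optim$emaDecay
      if (ed > 0) {
        Pema <- if (epoch == 1L) P
                else mapply(function(a, b) ed * a + (1 - ed) * b,
                            Pema, P, SIMPLIFY = FALSE)
      }
      losses[epoch] <- lv
      if (verbose && epoch %% 10L == 0L)
        message(sprintf("epoch %d loss %.4f", epoch, lv))
    }
    # Final inference pass: unmasked views, no dropout, averaged weights
    # if EMA is on.
    Pinf <- if (cfg@optim$emaDecay > 0) Pema else P
    evalInp <- list(
      AmHat = lapply(mv, gcnNormalize), AdHat = lapply(dv, gcnNormalize),
      trainPos = trainPos, forbidden = forbiddenPairs, scorePairs = NULL,
      Fm = Fm, Fd = Fd
    )
    fin <- .modelForward(Pinf, evalInp, cfg, training = FALSE)
    structure(list(
      params = Pinf, cfg = cfg,
      miRNAs = miRNAIds(ds), diseases = diseaseIds(ds),
      trainPairs = trainPairs, trainPos = trainPos,
      lossTrajectory = losses,
      embM = fin$embM, embD = fin$embD
    ), class = "HgtModel")
  })
}

#' @export
print.HgtModel <- function(x, ...) {
  cat(sprintf(
    "HgtModel (%s): %d miRNAs x %d diseases, %d training pairs\n  %d epochs, loss %.4f -> %.4f\n",
    x$cfg@ablation, length(x$miRNAs), length(x$diseases),
    nrow(x$trainPairs), length(x$lossTrajectory),
    x$lossTrajectory[1L], x$lossTrajectory[length(x$lossTrajectory)]
  ))
  invisible(x)
}

#' Score pairs with a trained model
#'
#' Uses the final-state embeddings (computed on the unmasked similarity
#' views, dropout off), so prediction is deterministic.
#'
#' @param model An `HgtModel` from [trainModel()].
#' @param pairs Two-column (miRNA index, disease index) matrix.
#' @return Numeric score vector in (0, 1).
#' @export
predictPairs <- function(model, pairs) {
  stopifnot(inherits(model, "HgtModel"))
  pairs <- .pairMatrix(pairs[, 1L], pairs[, 2L])
  scorePairs(model$embM, model$embD, pairs, .headParams(model$params))
}

#' ROC AUC via the rank statistic
#'
#' The normalised Mann-Whitney U: mean rank of the positive scores among
#' all scores, rescaled to \[0, 1\]. Errors on single-class label vectors.
#'
#' @param labels Binary labels.
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
aucScore <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: labels contain a single class")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integration)
#'
#' Scores are sorted in decreasing order and the PR curve is integrated as
#' a step function, equivalently the average of the precision at each
#' positive hit.
#'
#' @inheritParams aucScore
#' @return AUPRC in \[0, 1\].
#' @export
auprcScore <- function(labels, scores) {
  n1 <- sum(labels == 1)
  if (n1 == 0L) stop("AUPRC undefined without positives")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab == 1]) / n1
}

#' Thresholded and ranking classification metrics
#'
#' @param labels Binary labels.
#' @param scores Scores in \[0, 1\].
#' @param threshold Classification threshold (default 0.5).
#' @return Named vector: `acc`, `f1`, `recall`, `precision`, `auc`, `auprc`.
#' @export
computeMetrics <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(acc = mean(pred == labels), f1 = f1, recall = rec, precision = prec,
    auc = aucScore(labels, scores), auprc = auprcScore(labels, scores))
}

#' Evaluate a trained model on held-out pairs
#'
#' Guards that none of the evaluation pairs was trained on, scores them and
#' computes the full metric panel.
#'
#' @param model An `HgtModel`.
#' @param pairs Two-column held-out pair matrix.
#' @param labels Binary labels for `pairs`.
#' @return Named metric vector (see [computeMetrics()]).
#' @export
evaluateModel <- function(model, pairs, labels) {
  pairs <- .pairMatrix(pairs[, 1L], pairs[, 2L])
  seen <- paste(model$trainPairs$i, model$trainPairs$j)
  if (any(paste(pairs[, 1L], pairs[, 2L]) %in% seen))
    stop("evaluation pairs overlap the training pairs")
  computeMetrics(labels, predictPairs(model, pairs))
}

#' K-fold cross-validation of the full pipeline
#'
#' Trains one model per fold on the remaining folds' pairs and evaluates on
#' the held-out fold; every fold's held-out pairs (and the independent test
#' set) are passed to the hypergraph leakage guard. Fold seeds derive from
#' the configuration seed, so identical inputs give identical reports.
#'
#' @param ds An [AssociationDataset-class] with negatives sampled.
#' @param mirnaViews,diseaseViews Similarity view sets.
#' @param cfg A [ModelConfig-class].
#' @param split Optional [SplitSpec-class]; defaults to plain 5-fold
#'   cross-validation over all labelled pairs (no independent test set)
#'   under the configuration seed. Pass a split made with
#'   `testFraction = 0.2` to cross-validate inside the 8:2 training
#'   partition instead.
#' @param verbose Print per-fold metrics.
#' @return An [EvalReport-class]; fold models are attached as
#'   `attr(report, "models")`.
#' @export
crossValidate <- function(ds, mirnaViews, diseaseViews, cfg = modelConfig(),
                          split = NULL, verbose = FALSE) {
  if (is.null(split))
    split <- makeSplits(ds, testFraction = 0, kFolds = 5L, seed = cfg@seed)
  k <- length(split@folds)
  rows <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    idx <- split@folds[[f]]
    tr <- split@train[-idx, , drop = FALSE]
    ev <- split@train[idx, , drop = FALSE]
    held <- rbind(as.matrix(ev[, c("i", "j")]),
                  as.matrix(split@test[, c("i", "j")]))
    cfgF <- cfg
    cfgF@seed <- cfg@seed + f
    model <- trainModel(ds, mirnaViews, diseaseViews, cfgF,
                        trainPairs = tr, forbiddenPairs = held)
    met <- evaluateModel(model, as.matrix(ev[, c("i", "j")]), ev$label)
    rows[[f]] <- data.frame(fold = f, t(met))
    models[[f]] <- model
    if (verbose)
      message(sprintf("fold %d: AUC %.4f AUPRC %.4f", f, met["auc"], met["auprc"]))
  }
  perFold <- do.call(rbind, rows)
  rep <- new("EvalReport", perFold = perFold,
             means = colMeans(perFold[, -1L]), ranked = list())
  attr(rep, "models") <- models
  rep
}

#' Rank candidate miRNAs for a disease
#'
#' Scores every miRNA against the disease and returns the top of the
#' descending-score list (ties broken by miRNA identifier). Training
#' positives can be excluded, the usual setting when proposing novel
#' associations.
#'
#' @param model An `HgtModel`.
#' @param disease Disease identifier (or index).
#' @param topN Number of candidates to return (capped at km).
#' @param excludeTrainPositives Drop miRNAs whose association with this
#'   disease was a training positive (default `TRUE`).
#' @return Data frame with `rank`, `miRNA`, `score`.
#' @export
rankCandidates <- function(model, disease, topN = 20L,
                           excludeTrainPositives = TRUE) {
  stopifnot(inherits(model, "HgtModel"))
  j <- if (is.numeric(disease)) as.integer(disease)
       else match(.normalizeId(disease), .normalizeId(model$diseases))
  if (is.na(j) || j < 1L || j > length(model$diseases))
    stop("unknown disease: ", disease)
  mi <- seq_along(model$miRNAs)
  if (excludeTrainPositives) {
    pos <- model$trainPos[model$trainPos[, 2L] == j, 1L]
    mi <- setdiff(mi, pos)
  }
  sc <- predictPairs(model, cbind(mi, j))
  ord <- order(-sc, model$miRNAs[mi])
  top <- utils::head(ord, topN)
  data.frame(rank = seq_along(top), miRNA = model$miRNAs[mi][top],
             score = sc[top], row.names = NULL)
}
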