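#' Subset trials of a TrialSet
#'
#' @param x a \linkS4class{TrialSet}.
#' @param i trial indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TrialSet", function(x, i, j, ..., drop = FALSE) {
  new("TrialSet", data = x@data[i, , , drop = FALSE], labels = x@labels[i],
      fs = x@fs, channels = x@channels, trialWindow = x@trialWindow)
})

#' Fuse energy and manifold features
#'
#' \code{F = [100 * F1 ; F2]}: the two average-energy values are scaled by
#' 100 so their order of magnitude matches the manifold coordinates, then
#' the vectors are concatenated.
#'
#' @param F1 numeric length-2 average-energy feature.
#' @param F2 numeric length-d manifold feature (may be empty).
#' @return numeric vector of length 2 + d.
#' @examples
#' fuseFeatures(c(0.01, -0.02), c(1, 2, 3))
#' @export
fuseFeatures <- function(F1, F2 = numeric(0)) {
  if (length(F1) != 2L) stop("F1 must have length 2 (alpha and beta energies)")
  c(100 * as.numeric(F1), as.numeric(F2))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline: filter-bank names
#' and decomposition depth, time-block and wave selection (automatic with
#' manual override), the manifold parameters r, m, d, k, w, and the
#' cross-validation layout.  \code{selectionScope} controls whether the
#' time block and waves are selected on the training folds only (default,
#' leakage-free) or on the full set.
#'
#' @param firstLevel,laterLevel filter-bank names (see \code{\link{loadFilterBank}}).
#' @param J decomposition depth.
#' @param timeBlock \code{"auto"} or numeric(2) override (seconds or samples).
#' @param blockLengthS automatic time-block length in seconds.
#' @param waves \code{"auto"} or character vector of wave tags for the
#'   manifold feature (e.g. \code{"alpha"}).
#' @param waveFraction keep-fraction for automatic wave selection.
#' @param r,m,d,k,w manifold parameters (clamped to the data size at fit time).
#' @param folds number of cross-validation folds.
#' @param seed RNG seed for the fold assignment.
#' @param selectionScope \code{"train"} or \code{"all"}.
#' @return a list of class \code{ilmdConfig}.
#' @export
ilmdConfig <- function(firstLevel = "Antonini", laterLevel = "Qshift_c",
                       J = 4L, timeBlock = "auto", blockLengthS = 4,
                       waves = "auto", waveFraction = 0.5,
                       r = 52L, m = 14L, d = 5L, k = 24L, w = 4L,
                       folds = 10L, seed = 1L,
                       selectionScope = c("train", "all")) {
  selectionScope <- match.arg(selectionScope)
  if (!(identical(timeBlock, "auto") ||
        (is.numeric(timeBlock) && length(timeBlock) == 2L)))
    stop("timeBlock must be \"auto\" or numeric(2)")
  if (!(identical(waves, "auto") || is.character(waves)))
    stop("waves must be \"auto\" or a character vector of wave tags")
  stopifnot(J >= 1, folds >= 2, r >= 1, m >= 2, d >= 1, k >= 1, w >= 1)
  structure(list(firstLevel = firstLevel, laterLevel = laterLevel,
                 J = as.integer(J), timeBlock = timeBlock,
                 blockLengthS = blockLengthS, waves = waves,
                 waveFraction = waveFraction, r = as.integer(r),
                 m = as.integer(m), d = as.integer(d), k = as.integer(k),
                 w = as.integer(w), folds = as.integer(folds),
                 seed = as.integer(seed), selectionScope = selectionScope),
            class = "ilmdConfig")
}

# per-trial subband matrices for C3 and C4 (deterministic per trial, so
# computing them once for all trials leaks nothing across folds)
.subbandCache <- function(ts, cfg) {
  fb <- loadFilterBank(cfg$firstLevel, cfg$laterLevel)
  fs <- samplingRate(ts)
  out <- lapply(c(C3 = "C3", C4 = "C4"), function(ch) {
    m <- trialData(ts, ch)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    lapply(seq_len(nrow(m)), function(i) subbandSignals(m[i, ], cfg$J, fb, fs))
  })
  out$waves <- waveTags(fs, cfg$J)
  out
}

# trials x (J+1) matrix of per-subband average energy differences AE over
# the block; columns tagged by wave
.aeMatrix <- function(cache, block, fs) {
  idx <- block$min:block$max
  n <- length(cache$C3)
  ae <- t(vapply(seq_len(n), function(i) {
    e3 <- normalizedEnergy(cache$C3[[i]][idx, , drop = FALSE], fs)
    e4 <- normalizedEnergy(cache$C4[[i]][idx, , drop = FALSE], fs)
    colMeans(e3) - colMeans(e4)
  }, numeric(ncol(cache$C3[[1L]]))))
  colnames(ae) <- unname(cache$waves)
  ae
}

# fit the full pipeline on the training trials, classify the test trials
.fitIlmdFold <- function(ts, trainIdx, testIdx, cache, cfg) {
  fs <- samplingRate(ts)
  labels <- trialLabels(ts)
  selIdx <- if (cfg$selectionScope == "train") trainIdx else seq_len(nTrials(ts))
  block <- if (identical(cfg$timeBlock, "auto"))
    selectTimeBlock(ts[selIdx], blockLengthS = cfg$blockLengthS)
  else
    selectTimeBlock(ts, override = cfg$timeBlock)
  ae <- .aeMatrix(cache, block, fs)
  wsel <- if (identical(cfg$waves, "auto"))
    selectWaves(ae[selIdx, , drop = FALSE], labels[selIdx],
                waves = unname(cache$waves), fraction = cfg$waveFraction)
  else
    selectWaves(ae[selIdx, , drop = FALSE], labels[selIdx],
                waves = unname(cache$waves), override = cfg$waves)
  F1 <- ae[, c(which(cache$waves == "alpha")[1L],
               which(cache$waves == "beta")[1L]), drop = FALSE]
  Tr <- buildHighDimFeature(cache$C3, cache$C4, block, wsel$waves,
                            waveTags = unname(cache$waves))
  model <- fitLMvu(Tr[, trainIdx, drop = FALSE], r = cfg$r, m = cfg$m,
                   d = cfg$d, k = cfg$k, w = cfg$w)
  model@trainIds <- as.character(trainIdx)
  F2train <- embedding(model)
  F2test <- transformBatch(model, Tr[, testIdx, drop = FALSE])
  fuse <- function(F1m, F2m) cbind(100 * F1m, t(F2m))
  fit <- trainLda(fuse(F1[trainIdx, , drop = FALSE], F2train), labels[trainIdx])
  pred <- predictLda(fit, fuse(F1[testIdx, , drop = FALSE], F2test))
  list(pred = pred, truth = labels[testIdx], model = model, lda = fit,
       block = block, waves = wsel$waves, discriminative = wsel$discriminative,
       Tr = Tr, F1 = F1)
}

.stratifiedFolds <- function(labels, folds, seed) {
  n <- length(labels)
  fold <- integer(n)
  .withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Trials are partitioned into stratified folds with the given seed.  For
#' every fold the complete pipeline is fitted on the training trials only
#' -- time-block selection, wave selection, and the landmark-MVU fit --
#' and the held-out trials are embedded through the incremental
#' out-of-sample map (the model is never refitted) and classified with
#' LDA on the fused features.  Fold accuracies are averaged into the final
#' accuracy; the pooled confusion matrix yields Cohen's kappa.
#'
#' @param ts a \linkS4class{TrialSet}.
#' @param cfg an \code{\link{ilmdConfig}}.
#' @return a \linkS4class{CvResult}.
#' @export
crossValidate <- function(ts, cfg = ilmdConfig()) {
  n <- nTrials(ts)
  labels <- trialLabels(ts)
  if (n < cfg$folds) stop("fewer trials than folds")
  fold <- .stratifiedFolds(labels, cfg$folds, cfg$seed)
  cache <- .subbandCache(ts, cfg)
  acc <- numeric(cfg$folds)
  conf <- matrix(0L, 2L, 2L, dimnames = list(truth = c("left", "right"),
                                             pred = c("left", "right")))
  details <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    if (length(unique(labels[trainIdx])) < 2L || length(testIdx) == 0L)
      stop("fold ", f, " is degenerate; use stratified folds or another seed")
    r <- .fitIlmdFold(ts, trainIdx, testIdx, cache, cfg)
    acc[f] <- 100 * mean(r$pred == r$truth)
    conf <- conf + table(factor(r$truth, c("left", "right")),
                         factor(r$pred, c("left", "right")))
    details[[f]] <- list(block = r$block[c("min", "max", "seconds")],
                         waves = r$waves, accuracy = acc[f])
  }
  new("CvResult", foldAccuracies = acc, meanAccuracy = mean(acc),
      confusion = unclass(conf), kappa = cohenKappa(conf),
      seed = cfg$seed, folds = fold, details = details)
}

#' Run the end-to-end pipeline and emit a report
#'
#' Convenience wrapper around \code{\link{crossValidate}} that collects
#' the configuration, per-fold results, selected time blocks and waves,
#' the pooled confusion matrix and kappa into a report list, optionally
#' written as JSON.
#'
#' @param ts a \linkS4class{TrialSet}.
#' @param cfg an \code{\link{ilmdConfig}}.
#' @param reportPath optional path for a JSON report.
#' @return the \linkS4class{CvResult}, with the report in
#'   \code{attr(, "report")}.
#' @export
runIlmd <- function(ts, cfg = ilmdConfig(), reportPath = NULL) {
  cv <- crossValidate(ts, cfg)
  report <- list(
    config = unclass(cfg),
    nTrials = nTrials(ts), fs = samplingRate(ts),
    foldAccuracies = cv@foldAccuracies,
    meanAccuracy = cv@meanAccuracy,
    kappa = cv@kappa,
    confusion = cv@confusion,
    selections = lapply(cv@details, function(d)
      list(blockSeconds = d$block$seconds, waves = d$waves,
           accuracy = d$accuracy)))
  if (!is.null(reportPath))
    jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  attr(cv, "report") <- report
  cv
}

#' Robustness of the accuracy to the incremental neighbour count w
#'
#' Refits the fold models once and re-embeds the held-out trials for each
#' candidate w, returning the mean cross-validation accuracy per w.  The
#' landmark fit does not depend on w, so only the incremental embedding
#' and the classifier predictions are recomputed.
#'
#' @param ts a \linkS4class{TrialSet}.
#' @param cfg an \code{\link{ilmdConfig}}.
#' @param wValues integer vector of w values to evaluate.
#' @return named numeric vector of mean accuracies (percent) per w.
#' @export
wRobustness <- function(ts, cfg = ilmdConfig(), wValues = 2:12) {
  n <- nTrials(ts)
  labels <- trialLabels(ts)
  fold <- .stratifiedFolds(labels, cfg$folds, cfg$seed)
  cache <- .subbandCache(ts, cfg)
  perFold <- lapply(seq_len(cfg$folds), function(f) {
    trainIdx <- which(fold != f); testIdx <- which(fold == f)
    r <- .fitIlmdFold(ts, trainIdx, testIdx, cache, cfg)
    list(r = r, trainIdx = trainIdx, testIdx = testIdx)
  })
  acc <- vapply(wValues, function(wv) {
    mean(vapply(perFold, function(pf) {
      r <- pf$r
      F2test <- transformBatch(r$model, r$Tr[, pf$testIdx, drop = FALSE], w = wv)
      pred <- predictLda(r$lda, cbind(100 * r$F1[pf$testIdx, , drop = FALSE],
                                      t(F2test)))
      100 * mean(pred == labels[pf$testIdx])
    }, 0))
  }, 0)
  stats::setNames(acc, paste0("w", wValues))
}
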