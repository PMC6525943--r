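#' @rdname TrialSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("trialData", function(x, channel) standardGeneric("trialData"))

#' @rdname EmbeddingModel-accessors
#' @export
setGeneric("embedding", function(x) standardGeneric("embedding"))

#' @rdname EmbeddingModel-accessors
#' @export
setGeneric("landmarkKernel", function(x) standardGeneric("landmarkKernel"))

#' @rdname EmbeddingModel-accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' Accessors for TrialSet objects
#'
#' \code{nTrials}, \code{samplingRate}, \code{channelNames} and
#' \code{trialLabels} return the obvious fields; \code{trialData} returns
#' the trials x samples matrix of one channel.
#'
#' @param x a \code{TrialSet}.
#' @param channel channel name, e.g. \code{"C3"}.
#' @name TrialSet-accessors
NULL

#' Accessors for EmbeddingModel objects
#'
#' \code{embedding} returns the d x n training embedding Y,
#' \code{landmarkKernel} the optimised m x m kernel L, and
#' \code{modelParams} the free-parameter list (r, m, d, k, w).
#'
#' @param x an \code{EmbeddingModel}.
#' @name EmbeddingModel-accessors
NULL

setMethod("nTrials", "TrialSet", function(x) dim(x@data)[1L])
setMethod("samplingRate", "TrialSet", function(x) x@fs)
setMethod("channelNames", "TrialSet", function(x) x@channels)
setMethod("trialLabels", "TrialSet", function(x) x@labels)
setMethod("trialData", "TrialSet", function(x, channel) {
  ic <- match(channel, x@channels)
  if (is.na(ic)) stop("unknown channel: ", channel)
  x@data[, ic, , drop = TRUE]
})

setMethod("embedding", "EmbeddingModel", function(x) x@Y)
setMethod("landmarkKernel", "EmbeddingModel", function(x) x@L)
setMethod("modelParams", "EmbeddingModel", function(x) x@params)

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialSet: %d trials x %d channels (%s) x %d samples @ %g Hz\n",
              d[1L], d[2L], paste(object@channels, collapse = ","), d[3L], object@fs))
  if (d[1L] > 0L) {
    tab <- table(object@labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  cat(sprintf("  cue window: [%g, %g] s\n", object@trialWindow[1L], object@trialWindow[2L]))
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank: %s (level 1: %d,%d taps) + %s (levels >= 2: %d taps)\n",
              object@firstLevelName, length(object@lvl1a$h0$coef),
              length(object@lvl1a$h1$coef), object@laterLevelName,
              length(object@lvlqa$h0$coef)))
})

setMethod("show", "DtcwtCoefficients", function(object) {
  cat(sprintf("DtcwtCoefficients: %d levels, signal length %d, bank %s + %s\n",
              object@J, object@n, object@firstLevelName, object@laterLevelName))
})

setMethod("show", "EmbeddingModel", function(object) {
  p <- object@params
  cat(sprintf("EmbeddingModel: %d samples of dim %d embedded in %d-D (r=%d, m=%d, k=%d, w=%d)\n",
              ncol(object@X), nrow(object@X), nrow(object@Y),
              p$r, p$m, p$k, p$w))
})

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult: %d folds, mean accuracy %.2f%%, kappa %.3f\n",
              length(object@foldAccuracies), object@meanAccuracy, object@kappa))
})

setMethod("show", "TTestResult", function(object) {
  cat(sprintf("Two-sample pooled t-test (%s): t = %.4f, p = %.4g -> %s H0 at alpha = %g\n",
              object@alternative, object@statistic, object@p,
              if (object@reject) "reject" else "do not reject", object@alpha))
})
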