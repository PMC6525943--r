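#' @import methods
NULL

#' Multichannel single-trial EEG container
#'
#' Holds a trials x channels x samples array of EEG (microvolts) together
#' with per-trial class labels, the sampling rate, channel names and the
#' imagery cue window.  The C3 and C4 sensorimotor channels must be
#' present; Cz is carried through I/O but unused by the feature extractors.
#'
#' @slot data numeric array \code{[nTrials x nChannels x nSamples]}.
#' @slot labels character vector, one of \code{"left"}/\code{"right"} per trial.
#' @slot fs sampling rate in Hz.
#' @slot channels ordered channel names.
#' @slot trialWindow numeric length-2, cue interval in seconds from trial onset.
#' @exportClass TrialSet
setClass("TrialSet", representation(
  data = "array", labels = "character", fs = "numeric",
  channels = "character", trialWindow = "numeric"))

setValidity("TrialSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-D array (trials x channels x samples)")
  if (d[1L] != length(object@labels)) return("one label per trial required")
  if (d[2L] != length(object@channels)) return("channel count mismatch")
  if (!all(c("C3", "C4") %in% object@channels)) return("channels must contain C3 and C4")
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be a positive scalar")
  if (d[1L] > 0L && !all(object@labels %in% c("left", "right")))
    return("labels must be 'left' or 'right'")
  if (any(!is.finite(object@data))) return("data contains NaN/Inf")
  if (length(object@trialWindow) != 2L || diff(object@trialWindow) <= 0)
    return("trialWindow must be (start_s, end_s) with start < end")
  TRUE
})

#' Synthetic MI-EEG generator configuration
#'
#' Parameters of the two-class motor-imagery EEG simulator: geometry
#' (trials, sampling rate, duration, cue interval), rhythm amplitudes per
#' channel, ERD/ERS gains and the background-noise spectral exponent.
#' Defaults mirror a 128 Hz, 9 s, cue-at-3-s recording geometry.
#'
#' @slot nTrials number of trials (balanced across classes).
#' @slot fs sampling rate (Hz, >= 64 so the beta band is representable).
#' @slot durationS trial duration in seconds; \code{fs * durationS} must be integer.
#' @slot cueInterval imagery interval (seconds from trial onset).
#' @slot muBand,betaBand rhythm bands in Hz.
#' @slot muAmp,betaAmp per-channel RMS amplitudes (microvolts), named by channel.
#' @slot noiseAmp RMS of the 1/f background per channel (scalar).
#' @slot erdFactor multiplicative power attenuation (0,1] of the
#'   contralateral channel's rhythms during the cue.
#' @slot ersFactor power enhancement (>= 1) of the ipsilateral channel.
#' @slot noiseExponent exponent alpha of the 1/f^alpha background.
#' @slot rngSeed integer seed; identical configs give bit-identical data.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nTrials = "integer", fs = "numeric", durationS = "numeric",
  cueInterval = "numeric", muBand = "numeric", betaBand = "numeric",
  muAmp = "numeric", betaAmp = "numeric", noiseAmp = "numeric",
  erdFactor = "numeric", ersFactor = "numeric", noiseExponent = "numeric",
  rngSeed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@fs < 64) return("fs must be >= 64 Hz")
  if (object@muBand[1L] >= object@muBand[2L] ||
      object@betaBand[1L] >= object@betaBand[2L])
    return("invalid band: low >= high")
  if (object@betaBand[2L] > object@fs / 2) return("fs too low for requested bands")
  if (object@erdFactor <= 0 || object@erdFactor > 1) return("erdFactor must be in (0, 1]")
  if (object@ersFactor < 1) return("ersFactor must be >= 1")
  if (!.isWholeNumber(object@fs * object@durationS))
    return("fs * durationS must be an integer sample count")
  if (object@cueInterval[1L] < 0 || object@cueInterval[2L] > object@durationS ||
      diff(object@cueInterval) <= 0)
    return("cueInterval must lie inside the trial")
  TRUE
})

#' Dual-tree complex wavelet filter bank
#'
#' First-level biorthogonal analysis/synthesis filters plus the even-length
#' orthonormal Q-shift pair used from level 2 on.  Tree A carries the real
#' part of the transform; tree B's first-level filters are the same
#' odd-length filters delayed by one sample and its later-level low-pass is
#' the time reverse of tree A's, giving the approximate half-sample delay
#' between the trees' low-pass chains.
#'
#' @slot firstLevelName,laterLevelName catalogue names.
#' @slot lvl1a,lvl1b,lvlqa,lvlqb per-tree filter sets (lists with elements
#'   \code{h0,h1,f0,f1}, each \code{list(coef, t0)}).
#' @exportClass FilterBank
setClass("FilterBank", representation(
  firstLevelName = "character", laterLevelName = "character",
  lvl1a = "list", lvl1b = "list", lvlqa = "list", lvlqb = "list"))

#' Dual-tree complex wavelet coefficients
#'
#' Result of \code{\link{dtcwtForward}}: per-level coefficients for both
#' real trees, the original signal length and the padding bookkeeping
#' needed for exact inversion.
#'
#' @slot treeA,treeB per-tree analysis pyramids (periodic).
#' @slot J number of decomposition levels.
#' @slot n original signal length.
#' @slot n2 half-period of the symmetrized working signal.
#' @slot boundary \code{"reflect"} or \code{"periodic"}.
#' @slot firstLevelName,laterLevelName filter-bank names used.
#' @exportClass DtcwtCoefficients
setClass("DtcwtCoefficients", representation(
  treeA = "list", treeB = "list", J = "integer", n = "integer",
  n2 = "integer", boundary = "character",
  firstLevelName = "character", laterLevelName = "character"))

setValidity("DtcwtCoefficients", function(object) {
  if (object@J < 1L) return("J must be >= 1")
  TRUE
})

#' Fitted landmark-MVU embedding model
#'
#' Stores everything the incremental out-of-sample extension needs: the
#' training inputs X (columns are samples), the locally linear
#' reconstruction weights W, the landmark transform Q, the optimised
#' landmark kernel L with its eigendecomposition, the d x n embedding Y and
#' the free parameters (r, m, d, k, w).
#'
#' @slot X D x n training matrix.
#' @slot Y d x n embedding.
#' @slot W n x n reconstruction weight matrix (rows sum to 1 on neighbours).
#' @slot Q n x m landmark transform (landmark rows are the identity).
#' @slot L m x m landmark kernel (PSD within solver tolerance).
#' @slot eigenvalues,eigenvectors eigendecomposition of L (descending).
#' @slot params list with r, m, d, k, w.
#' @slot landmarks indices of the landmark columns of X.
#' @slot trainIds provenance identifiers of the training samples.
#' @slot solverStatus diagnostics from the SDP solve.
#' @exportClass EmbeddingModel
setClass("EmbeddingModel", representation(
  X = "matrix", Y = "matrix", W = "matrix", Q = "matrix", L = "matrix",
  eigenvalues = "numeric", eigenvectors = "matrix", params = "list",
  landmarks = "integer", trainIds = "character", solverStatus = "list"))

#' Cross-validation result
#'
#' @slot foldAccuracies per-fold accuracies in percent.
#' @slot meanAccuracy mean accuracy in percent.
#' @slot confusion pooled 2 x 2 confusion matrix (rows = truth).
#' @slot kappa Cohen's kappa of the pooled confusion matrix.
#' @slot seed RNG seed used for the fold assignment.
#' @slot folds fold index per trial.
#' @slot details per-fold selection decisions (time block, waves).
#' @exportClass CvResult
setClass("CvResult", representation(
  foldAccuracies = "numeric", meanAccuracy = "numeric", confusion = "matrix",
  kappa = "numeric", seed = "integer", folds = "integer", details = "list"))

#' Pooled two-sample t-test result
#'
#' @slot statistic pooled-variance t statistic.
#' @slot p p value (one-sided upper tail by default).
#' @slot alpha significance level.
#' @slot reject decision.
#' @slot meanA,meanB,varA,varB,nA,nB sample summaries.
#' @slot alternative "greater" or "two.sided".
#' @exportClass TTestResult
setClass("TTestResult", representation(
  statistic = "numeric", p = "numeric", alpha = "numeric", reject = "logical",
  meanA = "numeric", meanB = "numeric", varA = "numeric", varB = "numeric",
  nA = "integer", nB = "integer", alternative = "character"))
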