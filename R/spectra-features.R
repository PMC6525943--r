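#' Average power of a channel across trials of one class
#'
#' Samplewise average power: P(j) is the mean over the class's trials of
#' the squared j-th sample of the channel.
#'
#' @param ts a \linkS4class{TrialSet}.
#' @param channel channel name ("C3" or "C4" for the feature path).
#' @param classLabel "left" or "right".
#' @return numeric vector of length nSamples (microvolts squared).
#' @export
averagePowerSpectrum <- function(ts, channel, classLabel) {
  if (!channel %in% channelNames(ts)) stop("unknown channel: ", channel)
  idx <- which(trialLabels(ts) == classLabel)
  if (!length(idx)) stop("no trials with class label ", classLabel)
  m <- trialData(ts, channel)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  colMeans(m[idx, , drop = FALSE]^2)
}

#' Select the optimal time block
#'
#' Picks the contiguous window with the strongest class contrast in the
#' smoothed average power spectra of C3 and C4: the window of the
#' configured length, inside the search interval, maximising
#' \code{sum_j |(P_L^C3 - P_L^C4) - (P_R^C3 - P_R^C4)|(j)}; ties break to
#' the earliest start.  An explicit override (seconds, or 1-based sample
#' indices) always wins.  Sample blocks are 1-based inclusive
#' \code{[min, max]}, length \code{max - min + 1}.
#'
#' @param ts a \linkS4class{TrialSet} (the training trials).
#' @param blockLengthS window length in seconds; must exceed 2 s so at
#'   least one 2 fs sliding-energy window fits.
#' @param searchInterval numeric(2) seconds; default cue onset to trial end.
#' @param smoothWidth moving-average width in samples for the power
#'   spectra (default fs / 4); affects only the selection, never features.
#' @param override \code{NULL}, or numeric(2): seconds (values within the
#'   trial duration) or sample indices.
#' @param overrideUnit \code{"auto"}, \code{"seconds"} or \code{"samples"}.
#' @return list with integer \code{min}, \code{max} (samples), numeric
#'   \code{seconds}, and the contrast \code{score}.
#' @examples
#' ts <- simulateTrials(simConfig(nTrials = 20, rngSeed = 3))
#' selectTimeBlock(ts, override = c(3.5, 7.5))
#' @export
selectTimeBlock <- function(ts, blockLengthS = 4, searchInterval = NULL,
                            smoothWidth = NULL, override = NULL,
                            overrideUnit = c("auto", "seconds", "samples")) {
  fs <- samplingRate(ts)
  n <- dim(ts@data)[3L]
  durS <- n / fs
  overrideUnit <- match.arg(overrideUnit)
  if (!is.null(override)) {
    stopifnot(length(override) == 2L, override[1L] < override[2L])
    asSamples <- switch(overrideUnit,
      samples = TRUE, seconds = FALSE,
      auto = all(.isWholeNumber(override)) && override[2L] > durS)
    if (asSamples) {
      blk <- as.integer(round(override))
    } else {
      blk <- c(floor(override[1L] * fs) + 1L, floor(override[2L] * fs))
    }
    blk[1L] <- max(1L, blk[1L]); blk[2L] <- min(n, blk[2L])
    if (blk[2L] - blk[1L] <= 2 * fs)
      stop("time block must be longer than 2 s (one sliding window)")
    return(list(min = blk[1L], max = blk[2L],
                seconds = (c(blk[1L] - 1L, blk[2L])) / fs, score = NA_real_))
  }
  if (blockLengthS <= 2) stop("blockLengthS must exceed 2 s")
  if (is.null(searchInterval)) searchInterval <- c(ts@trialWindow[1L], durS)
  if (is.null(smoothWidth)) smoothWidth <- round(fs / 4)
  P <- lapply(c(left = "left", right = "right"), function(cl)
    lapply(c(C3 = "C3", C4 = "C4"), function(ch)
      .movingAverage(averagePowerSpectrum(ts, ch, cl), smoothWidth)))
  contrast <- abs((P$left$C3 - P$left$C4) - (P$right$C3 - P$right$C4))
  L <- as.integer(round(blockLengthS * fs))
  lo <- max(1L, as.integer(floor(searchInterval[1L] * fs)) + 1L)
  hi <- min(n, as.integer(floor(searchInterval[2L] * fs)))
  if (hi - lo + 1L < L) stop("no candidate window of required length in search interval")
  cs <- cumsum(c(0, contrast))
  starts <- lo:(hi - L + 1L)
  scores <- cs[starts + L] - cs[starts]
  best <- starts[which.max(scores)]     # which.max: earliest on ties
  list(min = best, max = best + L - 1L,
       seconds = c(best - 1L, best + L - 1L) / fs,
       score = max(scores))
}

#' Sliding-window energy of a subband signal
#'
#' Energy of a length-2fs window slid one sample at a time:
#' \code{E(l) = sum of squared samples in the window starting at l}.
#' Over a block of length \code{max - min + 1} this yields
#' \code{max - min - 2 fs + 2} values.
#'
#' @param x subband signal restricted to the time block.
#' @param fs sampling rate (window length is 2 fs samples).
#' @return numeric vector of window energies.
#' @export
slidingEnergy <- function(x, fs) {
  wlen <- as.integer(round(2 * fs))
  if (length(x) < wlen) stop("window longer than the supplied block")
  cs <- cumsum(c(0, x^2))
  nw <- length(x) - wlen + 1L
  cs[seq_len(nw) + wlen] - cs[seq_len(nw)]
}

#' Normalized sliding energies of all subbands
#'
#' Applies \code{\link{slidingEnergy}} to each subband column and
#' normalizes per window by the total energy over the J+1 subbands, so
#' each row sums to 1 (windows where every subband is exactly zero get an
#' equal split).
#'
#' @param subMat matrix (samples in block) x (J+1 subbands).
#' @param fs sampling rate.
#' @return matrix (windows) x (J+1) of normalized energies in [0, 1].
#' @export
normalizedEnergy <- function(subMat, fs) {
  E <- apply(subMat, 2L, slidingEnergy, fs = fs)
  if (is.null(dim(E))) E <- matrix(E, nrow = 1L, dimnames = list(NULL, colnames(subMat)))
  tot <- rowSums(E)
  zero <- tot <= 0
  tot[zero] <- 1
  En <- E / tot
  En[zero, ] <- 1 / ncol(E)
  En
}

#' Average energy feature F1 of one trial
#'
#' For each requested wave (alpha and beta by default) computes the mean
#' over sliding windows of the normalized subband energy on C3 minus that
#' on C4: \code{AE_wv = mean(ES_wv^C3) - mean(ES_wv^C4)}.  Contralateral
#' ERD during imagery makes the sign of AE_alpha class-informative.
#'
#' @param subC3,subC4 subband matrices of one trial restricted to the time
#'   block (columns as produced by \code{\link{subbandSignals}}).
#' @param fs sampling rate.
#' @param waves wave tags per subband column (default taken from the
#'   \code{waves} attribute of \code{subC3}).
#' @param select waves to extract (default \code{c("alpha", "beta")}).
#' @return named numeric vector of AE values (the F1 feature).
#' @export
averageEnergyFeature <- function(subC3, subC4, fs, waves = attr(subC3, "waves"),
                                 select = c("alpha", "beta")) {
  if (is.null(waves)) stop("wave tags missing")
  missing <- setdiff(select, waves)
  if (length(missing)) stop("no subband tagged: ", paste(missing, collapse = ", "))
  e3 <- normalizedEnergy(subC3, fs)
  e4 <- normalizedEnergy(subC4, fs)
  vapply(select, function(wv) {
    j <- which(waves == wv)[1L]
    mean(e3[, j]) - mean(e4[, j])
  }, 0)
}

#' Subject-adaptive wave selection
#'
#' Scores every candidate subband by the Fisher ratio of its
#' single-subband AE feature between the two classes on training data,
#' \code{(mean_L - mean_R)^2 / (var_L + var_R)}, and returns the
#' subband(s) scoring at least \code{fraction} of the best score.  An
#' explicit override wins.  If even the best score is negligible the
#' selection is flagged non-discriminative but still returns the
#' best-scoring band (ties to the lowest frequency).
#'
#' @param aeMat trials x subbands matrix of per-trial AE values (one
#'   column per candidate subband, computed on training trials).
#' @param labels class labels of the rows.
#' @param waves wave tag per column.
#' @param fraction keep bands scoring >= fraction * best (default 0.5).
#' @param override character vector of wave tags to force, or NULL.
#' @return list with \code{waves} (selected tags), \code{scores} (all
#'   Fisher ratios) and \code{discriminative} flag.
#' @export
selectWaves <- function(aeMat, labels, waves, fraction = 0.5, override = NULL) {
  if (!is.null(override)) {
    if (!all(override %in% waves)) stop("override wave(s) not among candidates")
    return(list(waves = override, scores = NULL, discriminative = NA))
  }
  if (length(unique(labels)) < 2L) stop("need both classes for wave selection")
  iL <- labels == "left"; iR <- labels == "right"
  scores <- apply(aeMat, 2L, function(v) {
    num <- (mean(v[iL]) - mean(v[iR]))^2
    den <- stats::var(v[iL]) + stats::var(v[iR])
    if (den <= 0) return(if (num > 0) Inf else 0)
    num / den
  })
  names(scores) <- waves
  best <- max(scores)
  disc <- best > 1e-3
  sel <- if (best > 0) which(scores >= fraction * best) else which.max(scores)
  if (!disc) sel <- which.max(scores)   # degenerate: deterministic single band
  list(waves = waves[sel], scores = scores, discriminative = disc)
}

#' High-dimensional channel-difference feature
#'
#' For each trial, the samplewise C3 minus C4 difference of the selected
#' subband signal over the time block \code{[min, max]} (length
#' \code{max - min + 1}); with several selected waves the per-wave vectors
#' are concatenated.  Trials are stacked as the columns of the training
#' matrix fed to the manifold learner.
#'
#' @param subListC3,subListC4 lists (one element per trial) of subband
#'   matrices as from \code{\link{subbandSignals}} (full trial length).
#' @param block time block list with \code{min}, \code{max} (samples).
#' @param waves selected wave tag(s).
#' @param waveTags wave tag per subband column (default from attributes).
#' @return matrix D x nTrials, D = (max - min + 1) * length(waves).
#' @export
buildHighDimFeature <- function(subListC3, subListC4, block, waves,
                                waveTags = attr(subListC3[[1L]], "waves")) {
  n <- dim(subListC3[[1L]])[1L]
  if (block$min < 1L || block$max > n) stop("time block outside signal bounds")
  idx <- block$min:block$max
  cols <- vapply(waves, function(wv) {
    j <- which(waveTags == wv)[1L]
    if (is.na(j)) stop("no subband tagged: ", wv)
    j
  }, 0L)
  vapply(seq_along(subListC3), function(u) {
    as.numeric(vapply(cols, function(j)
      subListC3[[u]][idx, j] - subListC4[[u]][idx, j], numeric(length(idx))))
  }, numeric(length(idx) * length(cols)))
}
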