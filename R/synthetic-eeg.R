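#' Build a simulator configuration
#'
#' Constructs a validated \linkS4class{SimConfig}.  The defaults mirror a
#' 128 Hz, 9 s trial geometry with the imagery cue at 3 s.  Sensorimotor
#' rhythms are synthesised as band-limited Gaussian noise (not pure tones)
#' over a 1/f^alpha background; during the cue the contralateral channel's
#' mu/beta power is attenuated by \code{erdFactor} and the ipsilateral
#' channel's enhanced by \code{ersFactor}, with raised-cosine ramps so the
#' gain change is smooth.
#'
#' @param nTrials number of trials; balanced across the two classes.
#' @param fs sampling rate in Hz (>= 64).
#' @param durationS trial length in seconds.
#' @param cueInterval numeric(2), imagery interval in seconds.
#' @param muBand,betaBand rhythm bands in Hz.
#' @param muAmp,betaAmp named per-channel RMS amplitudes (microvolts).
#' @param noiseAmp RMS of the 1/f background.
#' @param erdFactor multiplicative power attenuation in (0, 1] of the
#'   contralateral rhythms during the cue (1 = no effect).
#' @param ersFactor power enhancement >= 1 of the ipsilateral rhythms.
#' @param noiseExponent background spectral exponent alpha.
#' @param rngSeed integer seed.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nTrials = 10, rngSeed = 1)
#' @export
simConfig <- function(nTrials = 200L, fs = 128, durationS = 9,
                      cueInterval = c(3, 8),
                      muBand = c(8, 13), betaBand = c(13, 30),
                      muAmp = c(C3 = 2, Cz = 1, C4 = 2),
                      betaAmp = c(C3 = 1, Cz = 0.5, C4 = 1),
                      noiseAmp = 2, erdFactor = 0.3, ersFactor = 1.3,
                      noiseExponent = 1, rngSeed = 1L) {
  new("SimConfig", nTrials = as.integer(nTrials), fs = fs, durationS = durationS,
      cueInterval = cueInterval, muBand = muBand, betaBand = betaBand,
      muAmp = muAmp, betaAmp = betaAmp, noiseAmp = noiseAmp,
      erdFactor = erdFactor, ersFactor = ersFactor,
      noiseExponent = noiseExponent, rngSeed = as.integer(rngSeed))
}

# band-limited unit-RMS Gaussian noise via frequency-domain synthesis
.bandNoise <- function(n, fs, band) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                        # two-sided frequency axis
  mask <- f >= band[1L] & f <= band[2L]
  if (!any(mask)) stop("fs too low for requested band [", band[1L], ", ", band[2L], "]")
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * mask
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  x / stats::sd(x)
}

# unit-RMS 1/f^alpha background
.pinkNoise <- function(n, fs, alpha) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  amp <- ifelse(f > 0, f^(-alpha / 2), 0)
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * amp
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  x / stats::sd(x)
}

# raised-cosine gain envelope: 1 outside the cue, `gain` inside, 0.5 s ramps
.cueEnvelope <- function(n, fs, cue, gain, rampS = 0.5) {
  t <- (seq_len(n) - 1) / fs
  env <- rep(1, n)
  ramp <- min(rampS, diff(cue) / 2)
  up <- t >= cue[1L] & t < cue[1L] + ramp
  mid <- t >= cue[1L] + ramp & t <= cue[2L] - ramp
  dn <- t > cue[2L] - ramp & t <= cue[2L]
  env[mid] <- gain
  env[up] <- 1 + (gain - 1) * (1 - cos(pi * (t[up] - cue[1L]) / ramp)) / 2
  env[dn] <- 1 + (gain - 1) * (1 - cos(pi * (cue[2L] - t[dn]) / ramp)) / 2
  env
}

#' Generate synthetic two-class motor-imagery EEG
#'
#' Simulates \code{nTrials} single trials over channels C3, Cz, C4.  Each
#' channel is a 1/f^alpha background plus band-limited mu and beta rhythm
#' noise.  For class \code{"left"} the contralateral channel C4 has its
#' rhythm power multiplied by \code{erdFactor} during the cue interval
#' while C3 is scaled by \code{ersFactor}; class \code{"right"} mirrors
#' this.  Outside the cue interval the two classes are distributionally
#' identical.  Output is deterministic given \code{rngSeed}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{TrialSet}.
#' @examples
#' ts <- simulateTrials(simConfig(nTrials = 4, rngSeed = 42))
#' ts
#' @export
simulateTrials <- function(cfg) {
  validObject(cfg)
  channels <- names(cfg@muAmp)
  if (is.null(channels) || !all(c("C3", "C4") %in% channels))
    stop("muAmp must be named with channels including C3 and C4")
  n <- as.integer(round(cfg@fs * cfg@durationS))
  nt <- cfg@nTrials
  labels <- if (nt > 0L) rep(c("left", "right"), length.out = nt) else character(0)
  data <- array(0, dim = c(nt, length(channels), n))
  erdGain <- sqrt(cfg@erdFactor)      # factors act on power
  ersGain <- sqrt(cfg@ersFactor)
  .withSeed(cfg@rngSeed, {
    labels <- if (nt > 1L) sample(labels) else labels
    envErd <- .cueEnvelope(n, cfg@fs, cfg@cueInterval, erdGain)
    envErs <- .cueEnvelope(n, cfg@fs, cfg@cueInterval, ersGain)
    for (i in seq_len(nt)) {
      # contralateral to the imagined hand: left hand -> C4, right hand -> C3
      erdCh <- if (labels[i] == "left") "C4" else "C3"
      ersCh <- if (labels[i] == "left") "C3" else "C4"
      for (ci in seq_along(channels)) {
        ch <- channels[ci]
        env <- if (ch == erdCh) envErd else if (ch == ersCh) envErs else rep(1, n)
        mu <- .bandNoise(n, cfg@fs, cfg@muBand) * cfg@muAmp[ch]
        be <- .bandNoise(n, cfg@fs, cfg@betaBand) * cfg@betaAmp[ch]
        bg <- .pinkNoise(n, cfg@fs, cfg@noiseExponent) * cfg@noiseAmp
        data[i, ci, ] <- bg + env * (mu + be)
      }
    }
  })
  new("TrialSet", data = data, labels = labels, fs = cfg@fs,
      channels = channels, trialWindow = cfg@cueInterval)
}

#' Write / read a TrialSet as delimited text plus a JSON sidecar
#'
#' One comma-separated matrix per channel (\code{<channel>.csv}, one trial
#' per row) and a sidecar \code{trialset.json} holding \code{fs},
#' \code{labels}, \code{channels} and \code{trial_window}.  The round trip
#' is exact to float round-off.
#'
#' @param ts a \linkS4class{TrialSet} with at least one trial.
#' @param path directory to write into (created if missing).
#' @return \code{writeTrialSet} returns \code{path} invisibly;
#'   \code{readTrialSet} returns a \linkS4class{TrialSet}.
#' @export
writeTrialSet <- function(ts, path) {
  stopifnot(is(ts, "TrialSet"))
  if (nTrials(ts) == 0L) stop("empty dataset")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (ch in ts@channels) {
    m <- ts@data[, match(ch, ts@channels), , drop = FALSE]
    dim(m) <- dim(ts@data)[c(1L, 3L)]
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       file.path(path, paste0(ch, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  meta <- list(fs = ts@fs, labels = ts@labels, channels = ts@channels,
               trial_window = ts@trialWindow)
  jsonlite::write_json(meta, file.path(path, "trialset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTrialSet
#' @export
readTrialSet <- function(path) {
  sidecar <- file.path(path, "trialset.json")
  if (!file.exists(sidecar)) stop("missing sidecar trialset.json in ", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  mats <- lapply(meta$channels, function(ch) {
    f <- file.path(path, paste0(ch, ".csv"))
    if (!file.exists(f)) stop("channel matrix missing for ", ch)
    m <- as.matrix(utils::read.table(f, sep = ",", header = FALSE,
                                     colClasses = "numeric"))
    dimnames(m) <- NULL
    m
  })
  ns <- unique(vapply(mats, ncol, 0L)); nt <- unique(vapply(mats, nrow, 0L))
  if (length(ns) != 1L || length(nt) != 1L) stop("channel matrices disagree in shape")
  if (nt == 0L) stop("empty dataset")
  if (nt != length(meta$labels)) stop("label count does not match trial count")
  data <- array(0, dim = c(nt, length(meta$channels), ns))
  for (ci in seq_along(mats)) data[, ci, ] <- mats[[ci]]
  new("TrialSet", data = data, labels = as.character(meta$labels),
      fs = as.numeric(meta$fs), channels = as.character(meta$channels),
      trialWindow = as.numeric(meta$trial_window))
}
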