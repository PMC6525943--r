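# Public 1-D dual-tree complex wavelet interface.
#
# Two parallel real DWT trees (tree A = real part, tree B = imaginary
# part) run on a symmetrized periodic copy of the input, so inversion and
# single-subband reconstruction are exact to round-off for every
# catalogued bank and a constant input produces exactly vanishing detail
# bands.  Tree B's first level is delayed one sample and its Q-shift
# low-pass is the time reverse of tree A's, giving the cumulative
# half-sample offset per level that makes the dual tree nearly shift
# invariant.

#' Forward 1-D dual-tree complex wavelet transform
#'
#' Decomposes a real signal into J levels of complex detail coefficients
#' (tree A real, tree B imaginary) plus complex scaling coefficients.
#' Level 1 uses the odd-length first-level filters, levels >= 2 the
#' Q-shift filters.  With the default \code{boundary = "reflect"} the
#' signal is mirrored to a period-2n sequence before the periodic
#' transform; \code{"periodic"} treats the input as one period as-is.
#'
#' @param x real numeric vector.
#' @param J number of levels (>= 1).
#' @param fb a \linkS4class{FilterBank} from \code{\link{loadFilterBank}}.
#' @param boundary \code{"reflect"} (default) or \code{"periodic"}.
#' @return a \linkS4class{DtcwtCoefficients}.
#' @examples
#' fb <- loadFilterBank()
#' x <- sin(2 * pi * 10 * (0:511) / 128)
#' co <- dtcwtForward(x, J = 4, fb = fb)
#' max(abs(dtcwtInverse(co, fb) - x))
#' @export
dtcwtForward <- function(x, J, fb, boundary = c("reflect", "periodic")) {
  J <- as.integer(J)
  boundary <- match.arg(boundary)
  if (J < 1L) stop("J must be >= 1")
  n <- length(x)
  maxTaps <- max(vapply(c(fb@lvl1a, fb@lvlqa), function(f) length(f$coef), 0L))
  if (n < maxTaps) stop("signal shorter than filter support (", maxTaps, " taps)")
  if (n < 2L^J) stop("signal length must be at least 2^J")
  if (boundary == "reflect") {
    n2 <- as.integer(ceiling(n / 2^(J - 1L)) * 2^(J - 1L))
    xe <- c(x, rev(x))[seq_len(n2)]       # continue by reflection
    xs <- c(xe, rev(xe))                  # period 2 * n2, divisible by 2^J
  } else {
    n2 <- as.integer(ceiling(n / 2^J) * 2^J)
    xs <- c(x, x)[seq_len(n2)]            # periodize (recycle)
  }
  treeA <- .treeForward(xs, J, fb@lvl1a, fb@lvlqa)
  treeB <- .treeForward(xs, J, fb@lvl1b, fb@lvlqb)
  new("DtcwtCoefficients", treeA = treeA, treeB = treeB, J = J,
      n = as.integer(n), n2 = n2, boundary = boundary,
      firstLevelName = fb@firstLevelName, laterLevelName = fb@laterLevelName)
}

.checkBankMatch <- function(coeffs, fb) {
  if (coeffs@firstLevelName != fb@firstLevelName ||
      coeffs@laterLevelName != fb@laterLevelName)
    stop("coefficients were produced with bank ", coeffs@firstLevelName, "+",
         coeffs@laterLevelName, ", not ", fb@firstLevelName, "+", fb@laterLevelName)
}

#' Inverse 1-D dual-tree complex wavelet transform
#'
#' Inverts each tree with its synthesis filters and averages the two
#' reconstructions; with all coefficients retained this reproduces the
#' input to round-off.
#'
#' @param coeffs a \linkS4class{DtcwtCoefficients}.
#' @param fb the \linkS4class{FilterBank} used in the forward transform.
#' @return numeric vector of the original length.
#' @export
dtcwtInverse <- function(coeffs, fb) {
  .checkBankMatch(coeffs, fb)
  ra <- .treeInverse(coeffs@treeA, fb@lvl1a, fb@lvlqa)
  rb <- .treeInverse(coeffs@treeB, fb@lvl1b, fb@lvlqb)
  ((ra + rb) / 2)[seq_len(coeffs@n)]
}

#' Complex detail / scaling coefficients
#'
#' Returns the complex coefficients (tree A + i tree B) of one detail
#' level, or the complex scaling coefficients.
#'
#' @param coeffs a \linkS4class{DtcwtCoefficients}.
#' @param level detail level in 1..J.
#' @return complex vector.
#' @export
detailCoefficients <- function(coeffs, level) {
  level <- as.integer(level)
  if (level < 1L || level > coeffs@J) stop("level must be in 1..J")
  complex(real = coeffs@treeA$detail[[level]],
          imaginary = coeffs@treeB$detail[[level]])
}

#' @rdname detailCoefficients
#' @export
scalingCoefficients <- function(coeffs) {
  complex(real = coeffs@treeA$scaling, imaginary = coeffs@treeB$scaling)
}

#' Reconstruct a single subband signal
#'
#' Zeroes every coefficient level except the selected one and inverts,
#' giving the real time-domain subband signal (same length as the input).
#' \code{level = 0} (or \code{"A"}) selects the scaling subband A_J;
#' \code{level = j} selects Dt_j.  By linearity the J+1 subband signals
#' sum to the original signal.
#'
#' @param coeffs a \linkS4class{DtcwtCoefficients}.
#' @param level 0 (scaling) or detail level 1..J.
#' @param fb the matching \linkS4class{FilterBank}.
#' @return numeric vector of the original signal length.
#' @export
reconstructSubband <- function(coeffs, level, fb) {
  .checkBankMatch(coeffs, fb)
  if (length(level) != 1L || (is.character(level) && !nzchar(level)))
    stop("empty or invalid subband selector")
  if (is.character(level)) {
    if (toupper(level) != "A") stop("character selector must be \"A\"")
    level <- 0L
  }
  level <- as.integer(level)
  if (is.na(level) || level < 0L || level > coeffs@J)
    stop("level must be 0 (scaling) or 1..J")
  sel <- function(tree) {
    list(detail = lapply(seq_len(coeffs@J), function(j)
           if (j == level) tree$detail[[j]] else .zeroLike(tree$detail[[j]])),
         scaling = if (level == 0L) tree$scaling else .zeroLike(tree$scaling))
  }
  ra <- .treeInverse(sel(coeffs@treeA), fb@lvl1a, fb@lvlqa)
  rb <- .treeInverse(sel(coeffs@treeB), fb@lvl1b, fb@lvlqb)
  ((ra + rb) / 2)[seq_len(coeffs@n)]
}

#' All subband signals of one signal
#'
#' Convenience wrapper: forward transform plus reconstruction of the J+1
#' subband signals A_J, Dt_J, ..., Dt_1, returned as the columns of a
#' matrix with the subband frequency ranges and canonical EEG wave tags
#' attached as attributes.
#'
#' @param x real signal.
#' @param J number of levels.
#' @param fb a \linkS4class{FilterBank}.
#' @param fs sampling rate (Hz), used only for the attached metadata.
#' @param boundary boundary mode passed to \code{\link{dtcwtForward}}.
#' @return numeric matrix \code{length(x) x (J+1)} with columns named
#'   \code{A_J, Dt_J, ..., Dt_1}; attributes \code{freqRanges} and
#'   \code{waves}.
#' @export
subbandSignals <- function(x, J, fb, fs, boundary = "reflect") {
  co <- dtcwtForward(x, J, fb, boundary = boundary)
  out <- vapply(c(0L, seq.int(J, 1L)), function(l) reconstructSubband(co, l, fb),
                numeric(length(x)))
  colnames(out) <- c(paste0("A_", J), paste0("Dt_", seq.int(J, 1L)))
  attr(out, "freqRanges") <- subbandFrequencyRanges(fs, J)
  attr(out, "waves") <- waveTags(fs, J)
  out
}

#' Dyadic subband frequency ranges
#'
#' Frequency ranges of the J-level subband signals A_J, Dt_J, ..., Dt_1:
#' \code{[0, fs/2^(J+1)]} followed by the dyadic bands up to
#' \code{[fs/4, fs/2]}.  They tile \code{[0, fs/2]} without overlap.
#'
#' @param fs sampling rate in Hz (> 0).
#' @param J number of levels (>= 1).
#' @return a \code{(J+1) x 2} matrix with columns \code{lo}, \code{hi} and
#'   rows named as the subbands.
#' @examples
#' subbandFrequencyRanges(128, 4)   # 0-4, 4-8, 8-16, 16-32, 32-64 Hz
#' @export
subbandFrequencyRanges <- function(fs, J) {
  stopifnot(fs > 0, J >= 1)
  J <- as.integer(J)
  lo <- c(0, fs / 2^((J + 1L):2L))
  hi <- c(fs / 2^(J + 1L), fs / 2^(J:1L))
  m <- cbind(lo = lo, hi = hi)
  rownames(m) <- c(paste0("A_", J), paste0("Dt_", seq.int(J, 1L)))
  m
}

#' Canonical EEG wave tags for the subbands
#'
#' Tags each subband with the canonical EEG wave (delta 0-4, theta 4-8,
#' alpha 8-13, beta 13-30, gamma > 30 Hz) of greatest frequency overlap;
#' ties go to the lower-frequency wave.  At fs = 128 and J = 4 this maps
#' A_4 -> delta, Dt_4 -> theta, Dt_3 -> alpha, Dt_2 -> beta, Dt_1 -> gamma.
#'
#' @inheritParams subbandFrequencyRanges
#' @return named character vector, one wave per subband.
#' @export
waveTags <- function(fs, J) {
  fr <- subbandFrequencyRanges(fs, J)
  wv <- rbind(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 13),
              beta = c(13, 30), gamma = c(30, max(30.0001, fs / 2)))
  tags <- apply(fr, 1L, function(b) {
    ov <- pmax(0, pmin(b[2L], wv[, 2L]) - pmax(b[1L], wv[, 1L]))
    rownames(wv)[which.max(ov)]   # which.max keeps the first (lower) on ties
  })
  stats::setNames(tags, rownames(fr))
}
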