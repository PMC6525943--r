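# Low-level single-tree DWT engines.
#
# The transform used by the package is periodic: the input is reflected to
# a period-2n sequence (or periodized as-is), and each tree runs a
# circular DWT via FFT products.  The biorthogonal / orthonormal
# perfect-reconstruction identities are polynomial identities, so they
# hold exactly modulo z^P - 1 for every even period P: inversion is exact
# to round-off for every catalogued bank, constants produce exactly
# vanishing detail bands, and no boundary truncation enters.
#
# Filters carry an absolute origin t0 (sample index of the first tap);
# tree B's one-sample delay is expressed through these origins.

.filt <- function(coef, t0 = 0L) list(coef = as.numeric(coef), t0 = as.integer(t0))

# place filter taps on the circle of period P (periodization by wrapping)
.circFilt <- function(h, P) {
  v <- numeric(P)
  idx <- ((h$t0 + seq_along(h$coef) - 1L) %% P) + 1L
  for (j in seq_along(idx)) v[idx[j]] <- v[idx[j]] + h$coef[j]
  v
}

# analysis: a_k = sum_n x[n] h[n - 2k] (circular), kept at even positions
.cAnalyze <- function(x, h) {
  P <- length(x)
  hv <- .circFilt(h, P)
  corr <- Re(stats::fft(stats::fft(x) * Conj(stats::fft(hv)), inverse = TRUE)) / P
  corr[seq(1L, P, by = 2L)]
}

# synthesis contribution: y[n] = sum_k a_k f[n - 2k] (circular)
.cSynth <- function(a, f) {
  P <- 2L * length(a)
  up <- numeric(P)
  up[seq(1L, P, by = 2L)] <- a
  fv <- .circFilt(f, P)
  Re(stats::fft(stats::fft(up) * stats::fft(fv), inverse = TRUE)) / P
}

# J-level periodic analysis of a period-P signal with per-tree filters
.treeForward <- function(x, J, lvl1, lvlq) {
  detail <- vector("list", J)
  s <- x
  for (j in seq_len(J)) {
    fb <- if (j == 1L) lvl1 else lvlq
    detail[[j]] <- .cAnalyze(s, fb$h1)
    s <- .cAnalyze(s, fb$h0)
  }
  list(detail = detail, scaling = s)
}

.treeInverse <- function(tr, lvl1, lvlq) {
  J <- length(tr$detail)
  s <- tr$scaling
  for (j in rev(seq_len(J))) {
    fb <- if (j == 1L) lvl1 else lvlq
    s <- .cSynth(s, fb$f0) + .cSynth(tr$detail[[j]], fb$f1)
  }
  s
}

.zeroLike <- function(a) numeric(length(a))

# full (acyclic) convolution, used for filter diagnostics
.convFull <- function(a, b) {
  if (length(a) == 1L || length(b) == 1L) return(as.numeric(a %o% b))
  stats::convolve(a, rev(b), type = "open")
}
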