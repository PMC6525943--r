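# Generates the filter-bank catalogue under inst/extdata/filters/.
#
# First-level (odd-length, biorthogonal) banks come from maximally-flat
# halfband factorisation: P(z) = 2 [(1+z)(1+z^-1)/4]^K q(y), with
# y = (2 - z - z^^-1)/4 and q the Daubechies complement polynomial; the
# catalogue tap counts fix K and how the zeros at z = -1 and the q-roots
# are split between analysis and synthesis low-pass.  Antonini 9/7 and
# LeGall 5/3 are exactly the classical filters; the 5,7- and 13,19-tap
# near-symmetric banks use the split minimising the analysis/synthesis
# magnitude mismatch.
#
# Later-level (even-length, orthonormal) Q-shift banks are built on the
# paraunitary lattice, so orthonormality (hence perfect reconstruction)
# holds to machine precision.  The 10-tap (6 nonzero) and 14-tap filters
# are Kingsbury's published coefficient sets refitted onto the lattice
# (published 8-decimal roundings are ~1e-8 off the orthonormality
# manifold); the 10-, 16- and 18-tap variants without published tables
# are designed by lattice optimisation towards a quarter-sample group
# delay, one vanishing moment and minimal stopband energy.
#
# Run from the package root:  Rscript data-raw/make_filters.R

source("R/dwt-core.R")
set.seed(20251001)

outdir <- "inst/extdata/filters"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

pconv <- function(a, b) {       # exact polynomial product (handles complex)
  r <- rep(if (is.complex(a) || is.complex(b)) 0i else 0,
           length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    r[idx] <- r[idx] + a[i] * b
  }
  r
}

## ---------- biorthogonal first-level banks ----------------------------

# symmetric z-factor for a y-root: (y - y0) ~ c(1, -(2-4*y0), 1) up to scale
yroot_factor <- function(y0) c(1, -(2 - 4 * y0), 1)

build_sym <- function(nminus1, units) {
  # (1+z)^a (1+z^-1)^a with 2a = nminus1 zeros at -1, times unit factors
  h <- choose(nminus1, 0:nminus1)
  for (u in units) h <- pconv(h, u)
  h
}

# enumerate conjugate-closed subsets of q-roots with given z-degree
split_candidates <- function(roots, degH) {
  tol <- 1e-9
  units <- list(); isreal <- c()
  used <- rep(FALSE, length(roots))
  for (i in seq_along(roots)) {
    if (used[i]) next
    if (abs(Im(roots[i])) < tol) {
      units[[length(units) + 1L]] <- list(deg = 2L, fac = yroot_factor(Re(roots[i])))
      used[i] <- TRUE
    } else {
      j <- which(!used & abs(roots - Conj(roots[i])) < tol)[1]
      fac <- Re(pconv(yroot_factor(roots[i]) + 0i, yroot_factor(roots[j]) + 0i))
      units[[length(units) + 1L]] <- list(deg = 4L, fac = fac)
      used[i] <- used[j] <- TRUE
    }
  }
  nu <- length(units)
  out <- list()
  for (msk in 0:(2^nu - 1L)) {
    sel <- as.logical(bitwAnd(msk, 2^(seq_len(nu) - 1L)))
    if (sum(vapply(units[sel], `[[`, 0L, "deg")) == degH)
      out[[length(out) + 1L]] <- sel
  }
  list(units = units, sels = out)
}

maxflat_pair <- function(taps_h0, taps_f0) {
  stopifnot((taps_h0 + taps_f0 - 2L) %% 4L == 2L)
  K <- (taps_h0 + taps_f0) %/% 4L + ifelse((taps_h0 + taps_f0) %% 4L == 0, 0, 0)
  K <- (taps_h0 + taps_f0 - 2L + 2L) %/% 4L  # degree dh+df = 4K-2
  qc <- choose(K - 1 + 0:(K - 1), 0:(K - 1))       # ascending y powers
  roots <- if (K > 1) polyroot(qc) else complex(0)
  best <- NULL
  for (a in 0:K) {
    degH <- taps_h0 - 1L - 2L * a
    if (degH < 0 || degH > 2 * (K - 1)) next
    sc <- split_candidates(roots, degH)
    for (sel in sc$sels) {
      uh <- lapply(sc$units[sel], `[[`, "fac")
      uf <- lapply(sc$units[!sel], `[[`, "fac")
      h0 <- build_sym(2L * a, uh)
      f0 <- build_sym(2L * (K - a), uf)
      if (length(h0) != taps_h0 || length(f0) != taps_f0) next
      h0 <- h0 / sum(h0) * sqrt(2); f0 <- f0 / sum(f0) * sqrt(2)
      P <- pconv(h0, f0); cen <- (length(P) + 1L) %/% 2L
      evens <- P[seq(cen, length(P), by = 2L)][-1L]
      if (max(abs(evens)) > 1e-9) next
      w <- seq(0, pi, length.out = 257)
      mag <- function(h) abs(vapply(w, function(om)
        sum(h * exp(-1i * om * (seq_along(h) - 1))), 0i))
      score <- mean((mag(h0) - mag(f0))^2)
      if (is.null(best) || score < best$score)
        best <- list(h0 = h0, f0 = f0, score = score)
    }
  }
  stopifnot(!is.null(best))
  best
}

# high-pass derivation + alignment search, verified by exact circular probe
probe_pr <- function(bank) {
  set.seed(7)
  err <- 0
  for (P in c(64L, 50L)) {
    x <- rnorm(P)
    a0 <- .cAnalyze(x, bank$h0); a1 <- .cAnalyze(x, bank$h1)
    xr <- .cSynth(a0, bank$f0) + .cSynth(a1, bank$f1)
    err <- max(err, max(abs(xr - x)))
  }
  err
}

align_bank <- function(h0, f0) {
  c0 <- -(length(h0) - 1L) %/% 2L   # centre both low-passes at 0
  cf <- -(length(f0) - 1L) %/% 2L
  H0 <- .filt(h0, c0); F0 <- .filt(f0, cf)
  mod <- function(fl, delta, sgn) {
    n <- fl$t0 + delta + seq_along(fl$coef) - 1L
    .filt(sgn * (-1)^n * fl$coef, fl$t0 + delta)
  }
  for (d1 in -2:2) for (s1 in c(1, -1)) for (d2 in -2:2) for (s2 in c(1, -1)) {
    bank <- list(h0 = H0, h1 = mod(F0, d1, s1), f0 = F0, f1 = mod(H0, d2, s2))
    err <- tryCatch(probe_pr(bank), error = function(e) Inf)
    if (err < 1e-9) return(bank)
  }
  stop("no exact alignment found")
}

first_level <- list(
  antonini   = maxflat_pair(9L, 7L),
  legall     = maxflat_pair(5L, 3L),
  near_sym_a = maxflat_pair(5L, 7L),
  near_sym_b = maxflat_pair(13L, 19L)
)

## ---------- orthonormal Q-shift banks ---------------------------------

rotm <- function(t) matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)

lattice_h <- function(theta) {
  M <- length(theta)
  E <- array(0, c(2, 2, 1)); E[, , 1] <- rotm(theta[1])
  for (i in seq_len(M - 1L) + 1L) {
    d <- dim(E)[3]
    En <- array(0, c(2, 2, d + 1L))
    En[1, , 1:d] <- E[1, , , drop = FALSE]
    En[2, , 1:d + 1L] <- E[2, , , drop = FALSE]   # row 2 delayed by z^-1
    R <- rotm(theta[i])
    Eo <- array(0, dim(En))
    for (k in seq_len(d + 1L)) Eo[, , k] <- R %*% En[, , k]
    E <- Eo
  }
  d <- dim(E)[3]
  h0 <- numeric(2L * d); h1 <- numeric(2L * d)
  h0[seq(1, 2 * d, 2)] <- E[1, 1, ]; h0[seq(2, 2 * d, 2)] <- E[1, 2, ]
  h1[seq(1, 2 * d, 2)] <- E[2, 1, ]; h1[seq(2, 2 * d, 2)] <- E[2, 2, ]
  list(h0 = h0, h1 = h1)
}

fit_lattice <- function(target) {
  M <- length(target) / 2L
  obj <- function(th) sum((lattice_h(th)$h0 - target)^2)
  best <- NULL
  for (rep in 1:60) {
    th0 <- runif(M, -pi, pi)
    o <- try(optim(th0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-15)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
    if (best$value < 1e-13) break
  }
  stopifnot(best$value < 1e-12)  # within published rounding squared
  lattice_h(best$par)$h0
}

expmat <- function(w, N) exp(-1i * outer(w, 0:(N - 1)))  # |w| x N

freqresp <- function(h, w) drop(expmat(w, length(h)) %*% h)

group_delay <- function(h, w, E = expmat(w, length(h))) {
  n <- seq_along(h) - 1
  H <- drop(E %*% h)
  Hd <- drop(E %*% (n * h))
  Re(Hd * Conj(H)) / pmax(abs(H)^2, 1e-12)
}

design_qshift <- function(N) {
  M <- N / 2L
  tau <- (N - 1) / 2 - 0.25
  wpass <- seq(0.01, 0.45 * pi, length.out = 41)
  wstop <- seq(0.6 * pi, pi, length.out = 41)
  Ep <- expmat(wpass, N); Es <- expmat(wstop, N)
  # exact vanishing moment: lattice angles summing to -pi/4 (mod pi)
  full <- function(th) c(th, -pi / 4 - sum(th))
  obj <- function(th) {
    h <- lattice_h(full(th))$h0
    if (sum(h) < 0) h <- -h
    sb <- mean(abs(drop(Es %*% h))^2)
    gd <- mean((group_delay(h, wpass, Ep) - tau)^2)
    sb + 25 * gd
  }
  best <- NULL
  for (rep in 1:60) {
    th0 <- runif(M - 1L, -pi, pi)
    o <- try(optim(th0, obj, method = "BFGS",
                   control = list(maxit = 600, reltol = 1e-13)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  h <- lattice_h(full(best$par))$h0
  if (sum(h) < 0) h <- -h
  # canonical orientation: energy centred late enough that delay ~ tau
  gd0 <- mean(group_delay(h, wpass, Ep))
  if (abs(gd0 - ((N - 1) / 2 + 0.25)) < abs(gd0 - tau)) h <- rev(h)
  h
}

qshift_pub <- list(
  qshift_06 = c(0.03516384, 0, -0.08832942, 0.23389032, 0.76027237,
                0.58751830, 0, -0.11430184, 0, 0),
  qshift_b  = c(0.00325314, -0.00388321, 0.03466035, -0.03887280,
                -0.11720389, 0.27529538, 0.75614564, 0.56881042,
                0.01186609, -0.10671180, 0.02382538, 0.01702522,
                -0.00543948, -0.00455690)
)

qshift <- list()
qshift$qshift_06 <- fit_lattice(qshift_pub$qshift_06)
qshift$qshift_b  <- fit_lattice(qshift_pub$qshift_b)
qshift$qshift_a  <- design_qshift(10L)
qshift$qshift_c  <- design_qshift(16L)
qshift$qshift_d  <- design_qshift(18L)

## ---------- validation -------------------------------------------------

orth_resid <- function(h) {
  L <- length(h)
  max(abs(vapply(0:(L / 2 - 1), function(k)
    sum(h * c(rep(0, 2 * k), h)[1:L]), 0) - c(1, rep(0, L / 2 - 1))))
}

half_delay_offset <- function(h) {
  hb <- rev(h)
  cc <- pconv(h, rev(hb))          # correlation h0a vs h0b
  k <- which.max(abs(cc))
  lag <- k - length(h)             # integer lag
  y <- cc[(k - 1):(k + 1)]
  lag + 0.5 * (y[1] - y[3]) / (y[1] - 2 * y[2] + y[3])
}

for (nm in names(qshift)) {
  h <- qshift[[nm]]
  cat(sprintf("%-10s len %2d  orth %.2e  |H(-1)| %.2e  half-delay %+0.4f\n",
              nm, length(h), orth_resid(h),
              abs(sum(h * (-1)^(seq_along(h) - 1))), half_delay_offset(h)))
  stopifnot(orth_resid(h) < 1e-12)
}

banks <- list()
for (nm in names(first_level)) {
  b <- align_bank(first_level[[nm]]$h0, first_level[[nm]]$f0)
  err <- probe_pr(b)
  cat(sprintf("%-10s taps %d,%d  PR %.2e\n", nm,
              length(b$h0$coef), length(b$h1$coef), err))
  stopifnot(err < 1e-9)
  banks[[nm]] <- b
}

## ---------- write ------------------------------------------------------

wf <- function(fname, coef, origin) {
  con <- file(file.path(outdir, fname), "w")
  writeLines(sprintf("# origin %d", origin), con)
  writeLines(sprintf("%.17g", coef), con)
  close(con)
}

for (nm in names(banks)) {
  b <- banks[[nm]]
  for (role in c("h0", "h1", "f0", "f1"))
    wf(sprintf("%s_%s.txt", nm, role), b[[role]]$coef, b[[role]]$t0)
}
for (nm in names(qshift)) wf(sprintf("%s_h0a.txt", nm), qshift[[nm]], 0L)

cat("filter files written to", outdir, "\n")
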