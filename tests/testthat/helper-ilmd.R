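# shared fixtures and oracles, all generated in code

# curled 1-D arc in 2-D with the landmarks (first m input positions)
# spread evenly along the arc
arcData <- function(n = 30, m = 10, angle = 0.75 * pi, radius = 2) {
  tt <- seq(0, angle, length.out = n)
  lm <- round(seq(1, n, length.out = m))
  ord <- c(lm, setdiff(seq_len(n), lm))
  list(X = (rbind(cos(tt), sin(tt)) * radius)[, ord], arc = tt[ord],
       n = n, m = m)
}

# orthogonal Procrustes residual (rotation/reflection + translation),
# relative to the norm of the target configuration
procrustesResid <- function(A, B) {
  A <- t(A); B <- t(B)
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  s <- svd(crossprod(A, B))
  R <- s$v %*% t(s$u)
  sqrt(sum((A - B %*% R)^2) / sum(A^2))
}

# brute-force sum-to-one least squares via Lagrange elimination
bruteAffineWeights <- function(xt, Xn) {
  r <- ncol(Xn)
  Z <- Xn - xt
  G <- crossprod(Z)
  # KKT: [2G 1; 1' 0] [w; lambda] = [0; 1]
  K <- rbind(cbind(2 * G, 1), c(rep(1, r), 0))
  sol <- solve(K, c(rep(0, r), 1))
  sol[seq_len(r)]
}

.pairwiseSqTest <- function(X) as.matrix(dist(t(X)))^2

# FFT band power of a signal segment (periodogram oracle)
fftBandPower <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  keep <- f >= band[1] & f <= band[2] & f <= fs / 2
  sum(Mod(X[keep])^2) / n^2 * 2
}

# one cached slow end-to-end fixture set shared by the acceptance tests
.accEnv <- new.env()
acceptanceRuns <- function() {
  if (!is.null(.accEnv$runs)) return(.accEnv$runs)
  tsP <- simulateTrials(simConfig(nTrials = 200, rngSeed = 101))
  tsN <- simulateTrials(simConfig(nTrials = 200, erdFactor = 1, ersFactor = 1,
                                  rngSeed = 102))
  cfg <- ilmdConfig(folds = 10, seed = 1)
  .accEnv$runs <- list(
    planted = crossValidate(tsP, cfg),
    null = crossValidate(tsN, cfg),
    wSweep = wRobustness(tsP, cfg, wValues = 2:12))
  .accEnv$runs
}
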