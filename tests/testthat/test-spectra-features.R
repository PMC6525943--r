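# hand-built TrialSet with fully controlled samples
makeTrialSet <- function(dat, labels, fs = 128, window = c(3, 8)) {
  new("TrialSet", data = dat, labels = labels, fs = fs,
      channels = c("C3", "Cz", "C4"), trialWindow = window)
}

test_that("average power spectrum is the mean of squared samples", {
  n <- 16
  dat <- array(0, c(2, 3, n))
  a <- seq_len(n) / n
  dat[1, 1, ] <- a; dat[2, 1, ] <- -a
  ts <- makeTrialSet(dat, c("left", "left"))
  expect_equal(averagePowerSpectrum(ts, "C3", "left"), a^2)

  set.seed(9)
  dat2 <- array(rnorm(10 * 3 * n), c(10, 3, n))
  ts2 <- makeTrialSet(dat2, rep(c("left", "right"), 5))
  idx <- which(rep(c("left", "right"), 5) == "right")
  oracle <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in idx) s <- s + dat2[i, 3, j]^2
    oracle[j] <- s / length(idx)
  }
  expect_equal(averagePowerSpectrum(ts2, "C4", "right"), oracle,
               tolerance = 1e-12)
  expect_error(averagePowerSpectrum(ts2, "F3", "left"), "unknown channel")
  expect_error(averagePowerSpectrum(ts2["left" == trialLabels(ts2)], "C3", "right"),
               "no trials")
})

test_that("time-block override converts seconds to the paper's sample block", {
  ts <- simulateTrials(simConfig(nTrials = 4, rngSeed = 2))
  blk <- selectTimeBlock(ts, override = c(3.5, 7.5))
  expect_equal(blk$min, 449)           # floor(3.5 * 128) + 1
  expect_equal(blk$max, 960)           # floor(7.5 * 128)
  expect_equal(blk$max - blk$min + 1, 4 * 128)
  # sample-unit override accepted as well
  blk2 <- selectTimeBlock(ts, override = c(449, 960), overrideUnit = "samples")
  expect_equal(blk2[c("min", "max")], blk[c("min", "max")])
  expect_error(selectTimeBlock(ts, override = c(3, 4.5)), "longer than 2 s")
})

test_that("automatic selection finds the planted contrast window", {
  cfg <- simConfig(nTrials = 60, cueInterval = c(3, 7), erdFactor = 0.3,
                   rngSeed = 13)
  ts <- simulateTrials(cfg)
  blk <- selectTimeBlock(ts, blockLengthS = 3, searchInterval = c(0, 9))
  ov <- max(0, min(blk$seconds[2], 7) - max(blk$seconds[1], 3))
  expect_gte(ov / 3, 0.8)              # >= 80% of the window inside [3, 7] s

  # identical classes: contrast is ~0 but a window is still returned
  dat <- array(rep(rnorm(3 * 64 * 9), each = 4), c(4, 3, 64 * 9))
  tsEq <- makeTrialSet(dat, c("left", "right", "left", "right"), fs = 64)
  blkEq <- selectTimeBlock(tsEq, blockLengthS = 3, searchInterval = c(0, 9))
  expect_true(blkEq$min >= 1 && blkEq$max <= 64 * 9)
})

test_that("sliding energies conserve mass and scale quadratically", {
  fs <- 64
  set.seed(11)
  sub <- matrix(rnorm(5 * (4 * fs)), ncol = 5)
  En <- normalizedEnergy(sub, fs)
  expect_equal(nrow(En), 4 * fs - 2 * fs + 1)
  expect_lt(max(abs(rowSums(En) - 1)), 1e-12)
  expect_true(all(En >= 0 & En <= 1))

  # block of exactly 2 fs samples gives a single window
  expect_length(slidingEnergy(rnorm(2 * fs), fs), 1)
  expect_error(slidingEnergy(rnorm(2 * fs - 1), fs), "window longer")

  # one active subband takes all the normalized energy
  sub1 <- matrix(0, 3 * fs, 5); sub1[, 2] <- rnorm(3 * fs)
  En1 <- normalizedEnergy(sub1, fs)
  expect_equal(unname(En1[, 2]), rep(1, nrow(En1)))
  expect_equal(max(abs(En1[, -2])), 0)

  # scale equivariance
  expect_equal(normalizedEnergy(3.7 * sub, fs), En, tolerance = 1e-12)
  expect_equal(slidingEnergy(3.7 * sub[, 1], fs),
               3.7^2 * slidingEnergy(sub[, 1], fs), tolerance = 1e-10)
})

test_that("average energy feature matches a hand computation and is signed", {
  fs <- 1L   # window of 2 samples: tiny hand-checkable case
  waves <- c("delta", "alpha", "beta")
  subC3 <- cbind(c(1, 0, 1, 0), c(2, 1, 0, 1), c(0, 1, 1, 2))
  subC4 <- cbind(c(0, 1, 0, 1), c(1, 1, 1, 1), c(2, 0, 1, 0))
  # manual: windows of length 2, three windows; normalize per window
  manual <- function(S, col) {
    E <- vapply(seq_len(3), function(l) colSums(S[l:(l + 1), ]^2), numeric(3))
    mean(E[col, ] / colSums(E))
  }
  ae <- averageEnergyFeature(subC3, subC4, fs, waves = waves)
  expect_equal(unname(ae["alpha"]), manual(subC3, 2) - manual(subC4, 2),
               tolerance = 1e-12)
  expect_equal(unname(ae["beta"]), manual(subC3, 3) - manual(subC4, 3),
               tolerance = 1e-12)

  expect_equal(unname(averageEnergyFeature(subC3, subC3, fs, waves = waves)),
               c(0, 0))
  expect_error(averageEnergyFeature(subC3, subC4, fs, waves = c("a", "b", "c")),
               "no subband tagged")
})

test_that("planted left-hand ERD gives larger AE_alpha than right", {
  ts <- simulateTrials(simConfig(nTrials = 40, erdFactor = 0.3, rngSeed = 77))
  fb <- loadFilterBank()
  fs <- samplingRate(ts)
  blk <- selectTimeBlock(ts, override = c(3.5, 7.5))
  idx <- blk$min:blk$max
  ae <- vapply(seq_len(40), function(i) {
    s3 <- subbandSignals(trialData(ts, "C3")[i, ], 4, fb, fs)
    s4 <- subbandSignals(trialData(ts, "C4")[i, ], 4, fb, fs)
    averageEnergyFeature(s3[idx, ], s4[idx, ], fs,
                         waves = attr(s3, "waves"))["alpha"]
  }, 0)
  lab <- trialLabels(ts)
  expect_gt(mean(ae[lab == "left"]), mean(ae[lab == "right"]))
})

test_that("wave selection is adaptive, flagged, and overridable", {
  set.seed(21)
  n <- 40
  lab <- rep(c("left", "right"), 20)
  waves <- c("delta", "theta", "alpha", "beta", "gamma")
  ae <- matrix(rnorm(n * 5, sd = 0.05), n, 5)
  ae[lab == "left", 3] <- ae[lab == "left", 3] + 1   # effect only in alpha
  sel <- selectWaves(ae, lab, waves)
  expect_equal(sel$waves, "alpha")
  expect_true(sel$discriminative)

  aeN <- matrix(rnorm(n * 5, sd = 0.05), n, 5)
  selN <- selectWaves(aeN, lab, waves)
  expect_length(selN$waves, 1)

  selO <- selectWaves(ae, lab, waves, override = "delta")
  expect_equal(selO$waves, "delta")
  expect_error(selectWaves(ae, rep("left", n), waves), "both classes")
})

test_that("high-dimensional feature has the stated geometry", {
  set.seed(33)
  n <- 1100
  waves <- c("delta", "theta", "alpha", "beta", "gamma")
  mk <- function() {
    m <- matrix(rnorm(n * 5), n, 5)
    attr(m, "waves") <- waves
    m
  }
  l3 <- list(mk(), mk()); l4 <- list(mk(), mk())
  blk <- list(min = 450L, max = 1000L)
  Tr <- buildHighDimFeature(l3, l4, blk, "alpha", waveTags = waves)
  expect_equal(dim(Tr), c(551, 2))
  expect_equal(Tr[, 1], l3[[1]][450:1000, 3] - l4[[1]][450:1000, 3])

  Tr2 <- buildHighDimFeature(l3, l4, blk, c("alpha", "beta"), waveTags = waves)
  expect_equal(nrow(Tr2), 2 * 551)

  TrZ <- buildHighDimFeature(l3, l3, blk, "alpha", waveTags = waves)
  expect_equal(max(abs(TrZ)), 0)
  expect_error(buildHighDimFeature(l3, l4, list(min = 1L, max = n + 1L),
                                   "alpha", waveTags = waves),
               "outside signal bounds")
})
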