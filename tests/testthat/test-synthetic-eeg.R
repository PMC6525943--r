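test_that("generation is deterministic and balanced", {
  cfg <- simConfig(nTrials = 8, rngSeed = 99)
  a <- simulateTrials(cfg)
  b <- simulateTrials(cfg)
  expect_identical(a@data, b@data)
  expect_identical(a@labels, b@labels)
  expect_setequal(unique(a@labels), c("left", "right"))
  expect_equal(sum(a@labels == "left"), 4)
  expect_equal(dim(a@data), c(8, 3, 128 * 9))
  expect_false(any(!is.finite(a@data)))
})

test_that("planted ERD attenuates contralateral mu power during the cue", {
  # periodogram oracle: mu-band power of C4 in left trials, cue vs pre-cue
  cfg <- simConfig(nTrials = 60, erdFactor = 0.4, ersFactor = 1, rngSeed = 5)
  ts <- simulateTrials(cfg)
  fs <- samplingRate(ts)
  left <- which(trialLabels(ts) == "left")
  c4 <- trialData(ts, "C4")
  cue <- (floor(3.5 * fs) + 1):(7.5 * fs)       # sustained part of the cue
  pre <- 1:(3 * fs)
  pCue <- mean(vapply(left, function(i) fftBandPower(c4[i, cue], fs, c(8, 13)), 0))
  pPre <- mean(vapply(left, function(i) fftBandPower(c4[i, pre], fs, c(8, 13)), 0))
  expect_lt(pCue, 0.6 * pPre)
})

test_that("ERD is monotone in the attenuation factor", {
  pw <- vapply(c(0.3, 0.6, 1), function(erd) {
    ts <- simulateTrials(simConfig(nTrials = 50, erdFactor = erd,
                                   ersFactor = 1, rngSeed = 17))
    fs <- samplingRate(ts)
    left <- which(trialLabels(ts) == "left")
    c4 <- trialData(ts, "C4")
    cue <- (floor(3.5 * fs) + 1):(7.5 * fs)
    mean(vapply(left, function(i) fftBandPower(c4[i, cue], fs, c(8, 13)), 0))
  }, 0)
  expect_true(all(diff(pw) > 0))
})

test_that("null configuration leaves the classes distributionally equal", {
  ts <- simulateTrials(simConfig(nTrials = 80, erdFactor = 1, ersFactor = 1,
                                 rngSeed = 23))
  fs <- samplingRate(ts)
  cue <- (floor(3.5 * fs) + 1):(7.5 * fs)
  bp <- function(lab, ch) {
    m <- trialData(ts, ch)
    mean(vapply(which(trialLabels(ts) == lab),
                function(i) fftBandPower(m[i, cue], fs, c(8, 13)), 0))
  }
  expect_lt(abs(bp("left", "C4") / bp("right", "C4") - 1), 0.15)
  expect_lt(abs(bp("left", "C3") / bp("right", "C3") - 1), 0.15)
})

test_that("rhythm periodograms peak inside their nominal bands", {
  cfg <- simConfig(nTrials = 2, muAmp = c(C3 = 5, Cz = 5, C4 = 5),
                   betaAmp = c(C3 = 0, Cz = 0, C4 = 0),
                   noiseAmp = 1e-3, erdFactor = 1, ersFactor = 1, rngSeed = 31)
  ts <- simulateTrials(cfg)
  x <- trialData(ts, "C3")[1, ]
  fs <- samplingRate(ts)
  X <- Mod(stats::fft(x))^2
  f <- (0:(length(x) - 1)) * fs / length(x)
  peak <- f[f <= fs / 2][which.max(X[f <= fs / 2])]
  expect_gte(peak, 8); expect_lte(peak, 13)
  cfgB <- simConfig(nTrials = 2, muAmp = c(C3 = 0, Cz = 0, C4 = 0),
                    betaAmp = c(C3 = 5, Cz = 5, C4 = 5),
                    noiseAmp = 1e-3, erdFactor = 1, ersFactor = 1, rngSeed = 31)
  xb <- trialData(simulateTrials(cfgB), "C3")[1, ]
  Xb <- Mod(stats::fft(xb))^2
  peakB <- f[f <= fs / 2][which.max(Xb[f <= fs / 2])]
  expect_gte(peakB, 13); expect_lte(peakB, 30)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(fs = 32), "fs must be")
  expect_error(simConfig(muBand = c(13, 8)), "invalid band")
  expect_error(simConfig(fs = 64, betaBand = c(13, 40)), "fs too low")
  expect_error(simConfig(erdFactor = 1.2), "erdFactor")
  expect_error(simConfig(erdFactor = 0), "erdFactor")
  expect_error(simConfig(ersFactor = 0.9), "ersFactor")
})

test_that("trial-set I/O round-trips exactly and validates its contract", {
  ts <- simulateTrials(simConfig(nTrials = 4, rngSeed = 3))
  dir <- withr::local_tempdir()
  writeTrialSet(ts, dir)
  back <- readTrialSet(dir)
  expect_equal(back@data, ts@data, tolerance = 1e-12)
  expect_identical(back@labels, ts@labels)
  expect_identical(back@channels, ts@channels)
  expect_equal(back@fs, ts@fs)

  file.remove(file.path(dir, "C4.csv"))
  expect_error(readTrialSet(dir), "channel matrix missing")
  file.remove(file.path(dir, "trialset.json"))
  expect_error(readTrialSet(dir), "missing sidecar")

  empty <- new("TrialSet", data = array(0, c(0, 3, 8)), labels = character(0),
               fs = 128, channels = c("C3", "Cz", "C4"), trialWindow = c(3, 8))
  expect_error(writeTrialSet(empty, dir), "empty dataset")
})
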