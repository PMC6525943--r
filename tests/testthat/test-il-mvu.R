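arcModel <- function() {
  ad <- arcData(n = 40, m = 12, angle = 1.2 * pi)
  fitLMvu(ad$X, r = 2, m = 12, d = 2, k = 3, w = 4)
}

test_that("training points re-presented map to their training embeddings", {
  mod <- arcModel()
  for (i in seq_len(ncol(mod@X))) {
    iw <- incrementalWeights(mod, mod@X[, i])
    expect_true(i %in% iw$indices)
    expect_equal(iw$weights[iw$indices == i], 1)
    y <- mvuTransform(mod, mod@X[, i])
    expect_lt(sqrt(sum((y - mod@Y[, i])^2)),
              1e-6 * sqrt(sum(mod@Y[, i]^2)) + 1e-8)
  }
})

test_that("incremental weights are barycentric and match the oracle", {
  X <- rbind(c(0, 3))
  mod <- suppressWarnings(new("EmbeddingModel", X = X,
                              Y = matrix(c(0, 3), 1), W = diag(2),
                              Q = diag(2), L = diag(2), eigenvalues = c(1, 1),
                              eigenvectors = diag(2),
                              params = list(r = 1L, m = 2L, d = 1L, k = 1L, w = 2L),
                              landmarks = 1:2, trainIds = c("1", "2"),
                              solverStatus = list()))
  iw <- incrementalWeights(mod, 1, w = 2)
  expect_equal(sort(iw$weights), c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(sum(iw$weights), 1)

  set.seed(41)
  X2 <- matrix(rnorm(6 * 20), 6, 20)
  mod2 <- fitLMvu(X2, r = 4, m = 8, d = 3, k = 5)
  for (rep in 1:5) {
    xn <- rnorm(6)
    iw <- incrementalWeights(mod2, xn, w = 4)
    expect_equal(iw$weights,
                 bruteAffineWeights(xn, X2[, iw$indices, drop = FALSE]),
                 tolerance = 1e-8)
  }
  expect_error(incrementalWeights(mod2, rnorm(5)), "dimension mismatch")
})

test_that("affine points map to the same affine combination downstream", {
  mod <- arcModel()
  # midpoint of two mutually nearest training points, w = 2
  d2 <- .pairwiseSqTest(mod@X)
  diag(d2) <- Inf
  i <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  xm <- (mod@X[, i[1]] + mod@X[, i[2]]) / 2
  ym <- mvuTransform(mod, xm, w = 2)
  expect_equal(ym, (mod@Y[, i[1]] + mod@Y[, i[2]]) / 2, tolerance = 1e-8)
})

test_that("held-out manifold points land near the refit-oracle embedding", {
  n <- 40
  ad <- arcData(n = n, m = 12, angle = 1.2 * pi)
  mod <- fitLMvu(ad$X, r = 2, m = 12, d = 2, k = 3, w = 4)
  # held-out points between training samples
  tmid <- sort(ad$arc)[-1] - diff(sort(ad$arc)) / 2
  Xnew <- rbind(cos(tmid), sin(tmid)) * 2
  Ynew <- transformBatch(mod, Xnew)
  # oracle: refit with the held-out points included, align, compare
  Xall <- cbind(ad$X, Xnew)
  modAll <- fitLMvu(Xall, r = 2, m = 12, d = 2, k = 3)
  s <- svd(crossprod(t(modAll@Y[, seq_len(n)]) -
                       matrix(colMeans(t(modAll@Y[, seq_len(n)])), n, 2, byrow = TRUE),
                     t(mod@Y) - matrix(colMeans(t(mod@Y)), n, 2, byrow = TRUE)))
  R <- s$u %*% t(s$v)   # rotation refit -> original
  ctr <- colMeans(t(modAll@Y[, seq_len(n)]))
  ctr0 <- colMeans(t(mod@Y))
  refit <- t((t(modAll@Y[, -seq_len(n)]) -
                matrix(ctr, ncol(Xnew), 2, byrow = TRUE)) %*% R +
               matrix(ctr0, ncol(Xnew), 2, byrow = TRUE))
  diam <- max(dist(t(mod@Y)))
  expect_lt(mean(sqrt(colSums((Ynew - refit)^2))) / diam, 0.10)
})

test_that("no SDP is solved at transform time", {
  mod <- arcModel()
  before <- ilmd:::.sdpCallCount()
  invisible(transformBatch(mod, mod@X[, 1:5]))
  expect_identical(ilmd:::.sdpCallCount(), before)
})

test_that("model persistence round-trips transforms bit for bit", {
  mod <- arcModel()
  dir <- withr::local_tempdir()
  saveModel(mod, dir)
  back <- loadModel(dir)
  xn <- mod@X[, 3] + 0.05
  expect_identical(mvuTransform(back, xn), mvuTransform(mod, xn))
  # batch equals loop
  Xn <- mod@X[, 1:4] + 0.02
  batch <- transformBatch(mod, Xn)
  loop <- vapply(1:4, function(j) mvuTransform(mod, Xn[, j]), numeric(2))
  expect_identical(batch, loop)
  file.remove(file.path(dir, "params.json"))
  expect_error(loadModel(dir), "missing params.json")
})
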