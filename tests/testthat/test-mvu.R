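test_that("knn graph symmetrizes by union and matches a brute-force oracle", {
  X <- rbind(c(0, 1, 3))                 # 3 collinear points, k = 1
  eta <- knnGraph(X, 1)
  expect_equal(eta[2, 1], 1L)            # middle picks the nearer endpoint
  expect_equal(eta[2, 3], 1L)            # union rule links 3 -> 2 back
  expect_equal(eta[1, 3], 0L)
  expect_true(isSymmetric(eta))

  set.seed(7)
  X2 <- matrix(rnorm(3 * 20), 3, 20)
  expect_equal(knnGraph(X2, 19), matrix(1L, 20, 20) - diag(20L))

  k <- 4
  eta2 <- knnGraph(X2, k)
  D <- as.matrix(dist(t(X2)))
  oracle <- matrix(0L, 20, 20)
  for (i in 1:20) {
    nb <- order(D[i, -i])[1:k]
    oracle[i, (1:20)[-i][nb]] <- 1L
  }
  oracle <- pmax(oracle, t(oracle)); diag(oracle) <- 0L
  expect_identical(eta2, oracle)
  expect_error(knnGraph(X2, 20), "smaller than")
})

test_that("reconstruction weights solve the constrained least squares", {
  # 1-D {1, 2, 4}: x = 2 from neighbours {1, 4} -> (2/3, 1/3), zero error
  X <- rbind(c(1, 2, 4))
  W <- reconstructionWeights(X, 2)
  expect_equal(W[2, c(1, 3)], c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(drop(W[2, ] %*% t(X)), 2, tolerance = 1e-12)
  expect_equal(rowSums(W), rep(1, 3), tolerance = 1e-10)

  # duplicated point: weight concentrates on the duplicate
  X3 <- rbind(c(0, 1, 1, 5), c(0, 2, 2, 1))
  W3 <- reconstructionWeights(X3, 3)
  expect_equal(W3[2, 3], 1)              # exact duplicate of column 2
  expect_equal(W3[2, c(1, 4)], c(0, 0))

  # random instances vs brute-force Lagrange oracle
  set.seed(15)
  X4 <- matrix(rnorm(15 * 30), 15, 30)
  W4 <- reconstructionWeights(X4, 5)
  D <- as.matrix(dist(t(X4)))
  for (i in c(1, 8, 30)) {
    nb <- (1:30)[-i][order(D[i, -i])[1:5]]
    expect_equal(W4[i, nb], bruteAffineWeights(X4[, i], X4[, nb]),
                 tolerance = 1e-8)
  }
  expect_equal(max(abs(W4[cbind(1:30, 1:30)])), 0)  # diagonal zero
})

test_that("landmark transform has identity landmark rows and interpolates", {
  set.seed(19)
  X <- matrix(rnorm(4 * 12), 4, 12)
  W <- reconstructionWeights(X, 4)
  Q <- landmarkTransform(W, 5)
  expect_equal(Q[1:5, ], diag(5))
  expect_equal(rowSums(Q), rep(1, 12), tolerance = 1e-8)
  expect_equal(landmarkTransform(W, 12), diag(12))
})

test_that("SDP: degenerate, feasibility and isometry contracts hold", {
  # all points identical -> L = 0
  X0 <- matrix(1, 3, 6)
  eta0 <- matrix(1L, 6, 6); diag(eta0) <- 0L
  L0 <- solveLandmarkSdp(X0, diag(6), eta0)
  expect_equal(max(abs(L0)), 0)

  ad <- arcData(n = 30, m = 10)
  mod <- fitLMvu(ad$X, r = 2, m = 10, d = 2, k = 3)
  st <- mod@solverStatus
  maxd2 <- max(.pairwiseSqTest(ad$X))
  expect_lte(st$maxViolation, 1e-5 * maxd2)
  expect_lte(abs(st$centering), 1e-5)
  # neighbour distances in the embedding never exceed the input distances
  eta <- knnGraph(ad$X, 3)
  pr <- which(upper.tri(eta) & eta == 1L, arr.ind = TRUE)
  din <- sqrt(colSums((ad$X[, pr[, 1]] - ad$X[, pr[, 2]])^2))
  dout <- sqrt(colSums((mod@Y[, pr[, 1]] - mod@Y[, pr[, 2]])^2))
  expect_true(all(dout <= din * (1 + 1e-5)))
  # unfolding: embedding order matches arc-length order
  expect_equal(abs(cor(mod@Y[1, ], ad$arc, method = "spearman")), 1)
})

test_that("eigendecomposition embedding satisfies the Gram identity", {
  Y <- embedLandmarks(diag(c(4, 1)), 1)
  expect_equal(dim(Y), c(1, 2))
  expect_equal(sum(Y^2), 4)

  set.seed(23)
  A <- matrix(rnorm(25), 5)
  L <- crossprod(A)
  Yf <- embedLandmarks(L, 5)
  expect_equal(crossprod(Yf), L, tolerance = 1e-8)
  expect_equal(embedLandmarks(matrix(0, 4, 4), 2), matrix(0, 2, 4))
  expect_error(embedLandmarks(diag(c(1, -1)), 1), "not PSD")
})

test_that("embedAll applies the landmark rows exactly", {
  set.seed(29)
  Q <- rbind(diag(3), matrix(rnorm(6), 2))
  Ylm <- matrix(rnorm(6), 2)
  Y <- embedAll(Q, Ylm)
  expect_equal(Y[, 1:3], Ylm)
  expect_equal(Y, Ylm %*% t(Q), tolerance = 1e-12)
  expect_equal(embedAll(diag(3), Ylm[, 1:3]), Ylm[, 1:3])
  expect_error(embedAll(Q[, 1:2], Ylm), "dimension mismatch")
})

test_that("L-MVU with m = n matches a directly formulated full-kernel MVU", {
  set.seed(31)
  tt <- seq(0, pi, length.out = 10)
  X <- rbind(cos(tt), sin(tt), 0.1 * tt)
  mod <- fitLMvu(X, r = 3, m = 10, d = 2, k = 2)

  # direct full-kernel route: constraints assembled from raw distances,
  # centering basis and eigen-embedding computed here, barrier core only
  eta <- knnGraph(X, 2)
  E <- (eta + t(eta)) > 0
  pr <- which(upper.tri(E) & E, arr.ind = TRUE)
  b <- colSums((X[, pr[, 1]] - X[, pr[, 2]])^2)
  sc <- max(b)
  V <- qr.Q(qr(matrix(1, 10, 1)), complete = TRUE)[, -1]
  A <- (diag(10)[pr[, 1], ] - diag(10)[pr[, 2], ]) %*% V
  sol <- ilmd:::.sdpBarrier(crossprod(V), A, b / sc)
  K <- V %*% sol$M %*% t(V) * sc
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  Yd <- t(e$vectors[, 1:2] * rep(sqrt(pmax(e$values[1:2], 0)), each = 10))
  expect_lt(procrustesResid(mod@Y, Yd), 1e-3)
})

test_that("weight-row stochasticity holds across random fits", {
  set.seed(37)
  for (rep in 1:3) {
    X <- matrix(rnorm(6 * 15), 6, 15)
    W <- reconstructionWeights(X, 4)
    expect_lt(max(abs(rowSums(W) - 1)), 1e-10)
  }
})
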