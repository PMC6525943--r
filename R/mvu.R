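#' Symmetrized k-nearest-neighbour graph
#'
#' \code{eta[i, j] = 1} iff j is among i's k nearest neighbours by
#' Euclidean distance or vice versa (union rule); distance ties break to
#' the smaller index; the diagonal is zero.
#'
#' @param X D x n data matrix (columns are samples).
#' @param k number of neighbours, \code{1 <= k < n}.
#' @return n x n 0/1 integer matrix.
#' @export
knnGraph <- function(X, k) {
  n <- ncol(X)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k < 1L) stop("k must be at least 1")
  D2 <- .pairwiseSq(X)
  eta <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    ord <- order(D2[i, -i])          # stable: ties keep smaller index
    nbr <- (seq_len(n)[-i])[ord[seq_len(k)]]
    eta[i, nbr] <- 1L
  }
  eta <- pmax(eta, t(eta))
  diag(eta) <- 0L
  eta
}

.pairwiseSq <- function(X) {
  g <- crossprod(X)
  d <- diag(g)
  D2 <- outer(d, d, `+`) - 2 * g
  D2[D2 < 0] <- 0
  D2
}

# constrained least squares: min |xt - Xn w|^2 s.t. sum(w) = 1.
# If some neighbours coincide with xt the weight is split equally among
# them (the exact minimiser, deterministic tie-break).  Otherwise the
# sum-to-one constraint is eliminated (w = e1 + N v over the sum-zero
# subspace) and the reduced system solved by SVD least squares; singular
# values below 1e-10 of the largest are truncated, which regularises
# affinely dependent neighbourhoods (r may exceed the local rank) with
# the minimum-norm solution, deterministically.
.affineWeights <- function(xt, Xn, svTol = 1e-10) {
  r <- ncol(Xn)
  Z <- Xn - xt
  d2 <- colSums(Z^2)
  dup <- d2 <= 1e-24 * max(1, max(d2))
  if (any(dup)) {
    w <- numeric(r); w[dup] <- 1 / sum(dup)
    return(w)
  }
  if (r == 1L) return(1)
  N <- rbind(1, -diag(r - 1L))                # basis of the sum-zero space
  A <- Z %*% N
  rhs <- -Z[, 1L]
  sv <- svd(A)
  keep <- sv$d > svTol * max(sv$d)
  v <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], rhs)) / sv$d[keep])
  w <- c(1, numeric(r - 1L)) + drop(N %*% v)
  w
}

#' Locally linear reconstruction weights
#'
#' Each sample is reconstructed from its r nearest neighbours by the
#' weights minimising \code{|x_i - sum_j W_ij x_j|^2} under
#' \code{sum_j W_ij = 1}; non-neighbours get exactly zero, rows sum to 1.
#'
#' @param X D x n data matrix.
#' @param r number of reconstruction neighbours, \code{1 <= r < n}.
#' @return n x n weight matrix W.
#' @export
reconstructionWeights <- function(X, r) {
  n <- ncol(X)
  if (r >= n) stop("r must be smaller than the number of samples")
  D2 <- .pairwiseSq(X)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D2[i, -i])
    nbr <- (seq_len(n)[-i])[ord[seq_len(r)]]
    W[i, nbr] <- .affineWeights(X[, i], X[, nbr, drop = FALSE])
  }
  W
}

#' Landmark transform Q
#'
#' From the reconstruction weights, forms
#' \code{Lambda = (I - W)'(I - W)}, partitions it by landmark /
#' non-landmark samples and returns the n x m linear map whose landmark
#' rows are the identity and whose non-landmark block minimises the
#' reconstruction functional, \code{-Lambda_4^{-1} Lambda_3} in the
#' partitioned notation.  A singular non-landmark block is
#' ridge-regularised with a warning.
#'
#' @param W n x n reconstruction weight matrix.
#' @param m number of landmarks.
#' @param landmarks indices of the landmark samples (default the first m,
#'   in input order).
#' @return n x m matrix Q.
#' @export
landmarkTransform <- function(W, m, landmarks = seq_len(m)) {
  n <- nrow(W)
  m <- as.integer(m)
  stopifnot(m >= 1L, m <= n, length(landmarks) == m)
  Lam <- crossprod(diag(n) - W)
  if (m == n) return(diag(n))   # all samples are landmarks
  rest <- setdiff(seq_len(n), landmarks)
  L3 <- Lam[rest, landmarks, drop = FALSE]
  L4 <- Lam[rest, rest, drop = FALSE]
  Qo <- tryCatch(-solve(L4, L3), error = function(e) {
    warning("non-landmark block singular; ridge-regularised solve")
    -solve(L4 + diag(1e-8 * max(diag(L4)), nrow(L4)), L3)
  })
  Q <- matrix(0, n, m)
  Q[landmarks, ] <- diag(m)
  Q[rest, ] <- Qo
  Q
}

#' Eigendecomposition embedding of the landmark kernel
#'
#' Rows of the embedding are \code{sqrt(lambda_k) * V_k} for the d largest
#' eigenvalues of L (sorted descending), so the landmark Gram matrix is
#' reproduced when d = m.  Deterministic sign convention: the
#' largest-magnitude component of every eigenvector is positive.
#'
#' @param L m x m PSD landmark kernel.
#' @param d target dimension, \code{d <= m}.
#' @param tol PSD tolerance relative to the largest eigenvalue.
#' @return d x m matrix of landmark coordinates.
#' @export
embedLandmarks <- function(L, d, tol = 1e-6) {
  m <- nrow(L)
  stopifnot(d >= 1, d <= m)
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  scale <- max(abs(e$values), 1e-300)
  if (min(e$values) < -tol * scale) stop("kernel not PSD")
  lam <- pmax(e$values, 0)
  V <- e$vectors
  for (k in seq_len(m)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  t(V[, seq_len(d), drop = FALSE] * rep(sqrt(lam[seq_len(d)]), each = m))
}

#' Embed all samples through the landmark transform
#'
#' \code{Y = Ylm Q'}: each sample's embedding is its Q-row applied to the
#' landmark embedding; landmark columns of Y equal the landmark embedding
#' exactly because Q's landmark rows are the identity.
#'
#' @param Q n x m landmark transform.
#' @param Ylm d x m landmark embedding.
#' @return d x n embedding of all samples.
#' @export
embedAll <- function(Q, Ylm) {
  if (ncol(Q) != ncol(Ylm)) stop("dimension mismatch between Q and landmark embedding")
  Ylm %*% t(Q)
}

#' Fit a landmark-MVU embedding
#'
#' Chains the five training stages: reconstruction weights (r neighbours),
#' landmark transform (m landmarks, first-m by default), the landmark
#' semidefinite program (k-NN distance constraints), eigendecomposition
#' embedding of the kernel, and the linear extension to all samples.  The
#' training inputs and embedding are retained in the model so new samples
#' can be embedded incrementally without touching the SDP again.
#'
#' Parameter defaults r = 52, m = 14, d = 5, k = 24, w = 4 are clamped to
#' the data size (r, k <= n-1; m <= n; d < m).
#'
#' @param X D x n training matrix (columns are samples).
#' @param r,m,d,k,w free parameters (reconstruction neighbours, landmarks,
#'   target dimension, SDP constraint neighbours, incremental neighbours).
#' @param landmarks \code{"first"} (first m samples in input order, the
#'   default rule) or \code{"random"}.
#' @param seed RNG seed used only when \code{landmarks = "random"}.
#' @param tolGap SDP duality-gap target.
#' @return an \linkS4class{EmbeddingModel}.
#' @examples
#' X <- rbind(seq(0, 1, length.out = 12), 0.05 * sin(seq(0, 9, length.out = 12)))
#' fitLMvu(X, r = 3, m = 12, d = 2, k = 3)
#' @export
fitLMvu <- function(X, r = 52L, m = 14L, d = 5L, k = 24L, w = 4L,
                    landmarks = c("first", "random"), seed = 1L,
                    tolGap = 1e-9) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < 3L) stop("need at least 3 samples")
  landmarks <- match.arg(landmarks)
  r <- min(as.integer(r), n - 1L)
  k <- min(as.integer(k), n - 1L)
  m <- min(as.integer(m), n)
  d <- max(1L, min(as.integer(d), m - 1L, n - 1L))
  lmIdx <- if (landmarks == "first") seq_len(m) else
    sort(.withSeed(seed, sample(n, m)))
  eta <- knnGraph(X, k)
  W <- reconstructionWeights(X, r)
  Q <- landmarkTransform(W, m, lmIdx)
  L <- solveLandmarkSdp(X, Q, eta, tolGap = tolGap)
  status <- attr(L, "status")
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  Ylm <- embedLandmarks(L, d)
  Y <- embedAll(Q, Ylm)
  ids <- colnames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  attr(L, "status") <- NULL
  new("EmbeddingModel", X = X, Y = Y, W = W, Q = Q, L = L,
      eigenvalues = e$values, eigenvectors = e$vectors,
      params = list(r = r, m = m, d = d, k = k, w = as.integer(w)),
      landmarks = as.integer(lmIdx), trainIds = ids,
      solverStatus = if (is.null(status)) list() else status)
}
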