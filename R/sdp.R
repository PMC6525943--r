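# Interior-point solver for the landmark-MVU semidefinite program.
#
# The program  max <C, L>  s.t.  a_i' L a_i <= b_i,  sum_ij (QLQ')_ij = 0,
# L PSD  is solved after eliminating the centering constraint: PSD plus a
# vanishing quadratic form force L u = 0 for u = Q'1, so L = V M V' with V
# an orthonormal basis of the complement of u and M PSD of order m-1.
# What remains is a linear-objective SDP with rank-one inequality
# constraints, solved by a primal log-barrier path-following method
# (log det barrier on M, log barriers on the slacks); every iterate is
# strictly feasible, so constraint-I slacks and the centering identity
# hold by construction, and the duality gap bound (p + q)/t certifies
# near-optimality.

.ilmdEnv <- new.env(parent = emptyenv())
.ilmdEnv$sdpCalls <- 0L

.sdpCallCount <- function() .ilmdEnv$sdpCalls

# variable indexing for symmetric q x q matrices: diag first, then i<j
.symIndex <- function(q) {
  ut <- which(upper.tri(matrix(0, q, q)), arr.ind = TRUE)
  list(p1 = c(seq_len(q), ut[, 1L]), p2 = c(seq_len(q), ut[, 2L]),
       off = c(rep(FALSE, q), rep(TRUE, nrow(ut))))
}

.symToVec <- function(M, ix) M[cbind(ix$p1, ix$p2)]

.vecToSym <- function(v, q, ix) {
  M <- matrix(0, q, q)
  M[cbind(ix$p1, ix$p2)] <- v
  M[cbind(ix$p2, ix$p1)] <- v
  M
}

# maximize <C, M> s.t. rowwise a' M a <= b, M PSD;  A is p x q.
# Log-barrier path following with a warm start (M0, scaled into the strict
# interior) and a strict centering requirement before each t increase.
.sdpBarrier <- function(C, A, b, tolGap = 1e-9, mu = 10, maxOuter = 80,
                        maxNewtonStage = 2500, newtonBudget = 30000, M0 = NULL,
                        objBound = Inf) {
  # warm-started attempt first; on a centring failure fall back to a cold
  # start from the analytic-centre side
  if (!is.null(M0)) {
    out <- tryCatch(
      .sdpBarrierCore(C, A, b, tolGap, mu, maxOuter, maxNewtonStage,
                      newtonBudget, M0, objBound),
      error = function(e) if (grepl("unbounded", conditionMessage(e))) stop(e) else NULL)
    if (!is.null(out)) return(out)
  }
  .sdpBarrierCore(C, A, b, tolGap, mu, maxOuter, maxNewtonStage,
                  newtonBudget, NULL, objBound)
}

.sdpBarrierCore <- function(C, A, b, tolGap = 1e-9, mu = 10, maxOuter = 80,
                            maxNewtonStage = 2500, newtonBudget = 30000,
                            M0 = NULL, objBound = Inf) {
  q <- ncol(C)
  p <- nrow(A)
  ix <- .symIndex(q)
  nvar <- length(ix$p1)
  mult <- ifelse(ix$off, 2, 1)
  cvec <- .symToVec(C, ix) * mult
  # B[i, v] = a_i' E_v a_i
  B <- A[, ix$p1, drop = FALSE] * A[, ix$p2, drop = FALSE]
  B <- sweep(B, 2L, mult, `*`)
  rn <- rowSums(A^2)
  eps0 <- min(0.5 * min(b / pmax(rn, 1e-300)), max(b))
  m <- numeric(nvar); m[seq_len(q)] <- eps0   # fallback start eps0 * I
  warm <- FALSE
  if (!is.null(M0)) {
    M0 <- (M0 + t(M0)) / 2 + diag(1e-8 * max(1e-12, mean(diag(M0))), q)
    ev <- eigen(M0, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0) {
      v0 <- .symToVec(M0, ix)
      val <- drop(B %*% v0)
      sigma <- 0.8 * min(b / pmax(val, 1e-300))
      if (is.finite(sigma) && sigma > 0) {
        cand <- v0 * min(sigma, 1)
        cand[seq_len(q)] <- cand[seq_len(q)] + 0.5 * eps0
        if (all(b - drop(B %*% cand) > 0)) { m <- cand; warm <- TRUE }
      }
    }
  }
  fBarrier <- function(m, t) {
    M <- .vecToSym(m, q, ix)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    s <- b - drop(B %*% m)
    if (any(s <= 0)) return(Inf)
    -t * sum(cvec * m) - 2 * sum(log(diag(ch))) - sum(log(s))
  }
  ov <- as.numeric(ix$off)
  OO <- outer(ov, ov)
  OS <- outer(ov, ov, `+`)
  # warm starts sit near the optimal face: begin with the objective already
  # dominant so the first central point is nearby; cold starts begin gently
  t <- if (warm) max(1, (p + q) / (0.1 * max(1, abs(sum(cvec * m)))))
       else min(1, (p + q) / max(1, abs(sum(cvec * m))))
  outer <- 0L; newtTotal <- 0L
  repeat {
    outer <- outer + 1L
    centered <- FALSE
    for (it in seq_len(maxNewtonStage)) {
      newtTotal <- newtTotal + 1L
      M <- .vecToSym(m, q, ix)
      P <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
      if (is.null(P)) stop("SDP solver lost positive definiteness")
      s <- b - drop(B %*% m)
      gld <- P[cbind(ix$p1, ix$p2)] * mult
      g <- -t * cvec - gld + drop(crossprod(B, 1 / s))
      # Hessian of -log det in this basis: H_vw = tr(P E_v P E_w)
      T1 <- P[ix$p2, ix$p1, drop = FALSE] * P[ix$p1, ix$p2, drop = FALSE]
      T2 <- P[ix$p2, ix$p2, drop = FALSE] * P[ix$p1, ix$p1, drop = FALSE]
      H <- T1 * (1 + OO) + T2 * OS + crossprod(B * (1 / s), B / s)
      delta <- tryCatch(
        drop(chol2inv(chol(H + diag(1e-12 * max(diag(H)), nvar))) %*% (-g)),
        error = function(e) NULL)
      if (is.null(delta)) delta <- tryCatch(solve(H + diag(1e-8 * max(diag(H)), nvar), -g),
                                            error = function(e) stop("SDP Newton system singular"))
      lambda2 <- sum(-g * delta)
      if (!is.finite(lambda2)) stop("SDP solver diverged (non-finite Newton decrement)")
      if (lambda2 / 2 < 1e-6) { centered <- TRUE; break }
      f0 <- fBarrier(m, t)
      alpha <- 1
      repeat {
        fN <- fBarrier(m + alpha * delta, t)
        if (fN < f0 - 0.01 * alpha * lambda2) break
        alpha <- alpha * 0.6
        if (alpha < 1e-14) break
      }
      if (alpha < 1e-14) {    # line search exhausted: accept if near-centred
        if (lambda2 / 2 < 1e-3) centered <- TRUE
        break
      }
      m <- m + alpha * delta
      if (sum(cvec * m) > objBound)
        stop("SDP appears unbounded (is the neighbourhood graph connected?)")
    }
    if (!centered || newtTotal > newtonBudget)
      if (!centered)
        stop("SDP solver failed to centre (Newton decrement ",
             format(lambda2), " after ", it, " steps at barrier stage ", outer, ")")
    gap <- (p + q) / t
    if (gap < tolGap * max(1, abs(sum(cvec * m)))) break
    if (outer >= maxOuter || newtTotal > newtonBudget)
      stop("SDP solver failed to converge (gap ", format(gap), " after ",
           outer, " barrier stages, ", newtTotal, " Newton steps)")
    t <- t * mu
  }
  M <- .vecToSym(m, q, ix)
  list(M = (M + t(M)) / 2,
       status = list(converged = TRUE, barrierStages = outer,
                     newtonSteps = newtTotal, gap = (p + q) / t,
                     objective = sum(cvec * m)))
}

#' Solve the landmark-MVU semidefinite program
#'
#' Maximizes \code{trace(Q L Q')} over PSD landmark kernels L subject to
#' (I) the local distance constraints
#' \code{(QLQ')_ii - 2 (QLQ')_ij + (QLQ')_jj <= |x_i - x_j|^2} for every
#' neighbour pair of the k-NN graph, and (II) the global centering
#' \code{sum_ij (QLQ')_ij = 0}.  Solved by an interior-point log-barrier
#' method; the centering equality is enforced exactly by construction and
#' every constraint-I slack is nonnegative at the solution.
#'
#' @param X D x n data matrix (columns are samples).
#' @param Q n x m landmark transform from \code{\link{landmarkTransform}}.
#' @param eta n x n logical/0-1 neighbour indicator (symmetric).
#' @param tolGap relative duality-gap target.
#' @return m x m PSD matrix L with a \code{status} attribute (solver
#'   diagnostics, maximum constraint violation, centering residual).
#' @export
solveLandmarkSdp <- function(X, Q, eta, tolGap = 1e-9) {
  .ilmdEnv$sdpCalls <- .ilmdEnv$sdpCalls + 1L
  n <- ncol(X); m <- ncol(Q)
  stopifnot(nrow(Q) == n, all(dim(eta) == c(n, n)))
  E <- (eta + t(eta)) > 0
  pr <- which(upper.tri(E) & E, arr.ind = TRUE)
  if (nrow(pr) == 0L) stop("neighbour graph has no edges")
  # a disconnected constraint graph leaves the variance objective unbounded
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(E[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen))
    stop("neighbourhood graph is disconnected; increase k")
  b <- colSums((X[, pr[, 1L], drop = FALSE] - X[, pr[, 2L], drop = FALSE])^2)
  if (max(b) <= 1e-28) {   # all constrained points coincide: L = 0 is optimal
    L <- matrix(0, m, m)
    attr(L, "status") <- list(converged = TRUE, degenerate = TRUE,
                              maxViolation = 0, centering = 0)
    return(L)
  }
  scale <- max(b)
  b <- pmax(b / scale, 1e-10)
  u <- colSums(Q)
  if (sqrt(sum(u^2)) > 1e-10) {
    V <- qr.Q(qr(matrix(u, ncol = 1L)), complete = TRUE)[, -1L, drop = FALSE]
  } else V <- diag(m)
  A <- (Q[pr[, 1L], , drop = FALSE] - Q[pr[, 2L], , drop = FALSE]) %*% V
  C <- crossprod(Q %*% V)
  # warm start at the least-squares landmark kernel of the input Gram:
  # the identity embedding is (nearly) feasible and close to the central
  # path for locally isometric data
  M0 <- tryCatch({
    Xc <- X - rowMeans(X)
    K <- crossprod(Xc) / scale
    QtQ <- crossprod(Q)
    L0 <- solve(QtQ, t(Q) %*% K %*% Q) %*% solve(QtQ)
    crossprod(V, (L0 + t(L0)) / 2) %*% V
  }, error = function(e) NULL)
  sol <- .sdpBarrier(C, A, b, tolGap = tolGap, M0 = M0,
                     objBound = 100 * n^2 * max(1, max(rowSums(Q^2))))
  L <- V %*% sol$M %*% t(V) * scale
  L <- (L + t(L)) / 2
  G <- Q %*% L %*% t(Q)
  dG <- diag(G)
  viol <- max(0, max(dG[pr[, 1L]] - 2 * G[cbind(pr[, 1L], pr[, 2L])] +
                     dG[pr[, 2L]] - b * scale))
  st <- sol$status
  st$maxViolation <- viol
  st$centering <- sum(G)
  attr(L, "status") <- st
  L
}
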