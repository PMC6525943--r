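# Two-class linear discriminant analysis with pooled within-class
# covariance and equal priors.  Implemented directly (rather than via an
# external fit) so that a conditioning-triggered shrinkage fallback can be
# applied: when the pooled covariance condition number exceeds 1e8 it is
# shrunk towards the scaled identity until well conditioned.

#' Train a two-class LDA classifier
#'
#' @param X n x p feature matrix (rows are trials).
#' @param labels class label per row; exactly two classes required.
#' @param condThresh conditioning threshold that triggers shrinkage.
#' @return an object of class \code{ilmdLda}.
#' @export
trainLda <- function(X, labels, condThresh = 1e8) {
  X <- as.matrix(X)
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("need exactly two classes, got ", length(cls))
  i1 <- labels == cls[1L]; i2 <- labels == cls[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 training trials")
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[i2, , drop = FALSE])
  S <- ((n1 - 1) * stats::cov(X[i1, , drop = FALSE]) +
        (n2 - 1) * stats::cov(X[i2, , drop = FALSE])) / (n1 + n2 - 2)
  cond <- function(M) {
    d <- svd(M, nu = 0, nv = 0)$d
    if (min(d) <= 0) Inf else max(d) / min(d)
  }
  shrunk <- 0
  gamma <- 1e-4
  tgt <- mean(diag(S))
  while ((!all(is.finite(S)) || cond(S) > condThresh) && gamma <= 1) {
    S <- (1 - gamma) * S + gamma * tgt * diag(ncol(X))
    shrunk <- gamma
    gamma <- gamma * 10
  }
  wv <- solve(S, mu2 - mu1)
  structure(list(classes = cls, w = wv,
                 threshold = sum(wv * (mu1 + mu2)) / 2,
                 shrinkage = shrunk),
            class = "ilmdLda")
}

#' @rdname trainLda
#' @param fit an \code{ilmdLda} object.
#' @return \code{predictLda}: character vector of predicted labels.
#' @export
predictLda <- function(fit, X) {
  X <- as.matrix(X)
  score <- drop(X %*% fit$w)
  ifelse(score > fit$threshold, fit$classes[2L], fit$classes[1L])
}
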