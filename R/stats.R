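#' Cohen's kappa of a 2 x 2 confusion matrix
#'
#' Chance-corrected agreement \code{(p_o - p_e) / (1 - p_e)} with the
#' usual marginal expectation \code{p_e}.  The degenerate all-one-cell
#' case (\code{p_e = 1}) is defined as 0 with a warning.
#'
#' @param cm 2 x 2 nonnegative confusion matrix (rows = truth).
#' @return kappa in [-1, 1].
#' @examples
#' cohenKappa(matrix(c(40, 5, 10, 45), 2))
#' @export
cohenKappa <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == 2L) || any(cm < 0)) stop("cm must be a nonnegative 2 x 2 matrix")
  N <- sum(cm)
  if (N <= 0) stop("confusion matrix is empty")
  po <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (pe >= 1) {
    warning("degenerate confusion matrix (all mass in one class); kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Pooled two-sample t-test
#'
#' The pooled-variance statistic
#' \code{t = (mean(a) - mean(b)) / sqrt(((nA-1) sA^2 + (nB-1) sB^2) /
#' (nA + nB - 2) * (1/nA + 1/nB))} with \code{nA + nB - 2} degrees of
#' freedom.  The default alternative is the upper one-sided tail
#' \code{P(T > t)} with rejection at \code{p <= alpha}; a two-sided option
#' is available.
#'
#' @param a,b numeric accuracy (or other) samples, each of length >= 2.
#' @param alpha significance level.
#' @param alternative \code{"greater"} (one-sided, default) or
#'   \code{"two.sided"}.
#' @return a \linkS4class{TTestResult}.
#' @examples
#' twoSampleTTest(c(92, 93, 91), c(90, 89, 90))
#' @export
twoSampleTTest <- function(a, b, alpha = 0.05,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  nA <- length(a); nB <- length(b)
  if (nA < 2L || nB < 2L) stop("each sample needs at least 2 values")
  mA <- mean(a); mB <- mean(b)
  vA <- stats::var(a); vB <- stats::var(b)
  df <- nA + nB - 2L
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tstat <- if (se > 0) (mA - mB) / se else if (mA == mB) 0 else sign(mA - mB) * Inf
  p <- switch(alternative,
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
  new("TTestResult", statistic = tstat, p = p, alpha = alpha,
      reject = p <= alpha, meanA = mA, meanB = mB, varA = vA, varB = vB,
      nA = as.integer(nA), nB = as.integer(nB), alternative = alternative)
}
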