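# Incremental out-of-sample extension: a new point is embedded by
# reconstructing it from its w nearest training samples in the input
# space (sum-to-one least squares) and carrying the same weights to the
# training embedding.  No SDP is touched at test time.

#' Incremental reconstruction weights of a new sample
#'
#' Finds the w nearest training samples (Euclidean; ties to the smaller
#' index) and the weights minimising
#' \code{|x_new - sum_j IW_j x_j|^2} subject to \code{sum_j IW_j = 1},
#' using the same regularised solver as \code{\link{reconstructionWeights}}.
#'
#' @param model a fitted \linkS4class{EmbeddingModel}.
#' @param xNew numeric vector of length D.
#' @param w number of incremental neighbours (default from the model).
#' @return list with \code{indices} (Ns) and \code{weights} (IW).
#' @export
incrementalWeights <- function(model, xNew, w = modelParams(model)$w) {
  X <- model@X
  n <- ncol(X)
  if (n == 0L) stop("empty model")
  if (length(xNew) != nrow(X)) stop("dimension mismatch: expected ", nrow(X))
  w <- min(as.integer(w), n)
  d2 <- colSums((X - xNew)^2)
  ns <- order(d2)[seq_len(w)]          # stable order: ties to smaller index
  iw <- .affineWeights(xNew, X[, ns, drop = FALSE])
  list(indices = ns, weights = iw)
}

#' Embed new samples on the trained manifold
#'
#' \code{y_new = sum_j IW_j y_j} over the w nearest training neighbours:
#' the model is never refitted and no semidefinite program is solved, which
#' is the point of the incremental extension.  A matrix input is embedded
#' column by column.
#'
#' @param model a fitted \linkS4class{EmbeddingModel}.
#' @param xNew numeric vector (length D) or D x nNew matrix.
#' @param w number of incremental neighbours (default from the model).
#' @return d-vector, or d x nNew matrix for matrix input.
#' @export
mvuTransform <- function(model, xNew, w = modelParams(model)$w) {
  if (is.matrix(xNew)) {
    out <- vapply(seq_len(ncol(xNew)), function(j)
      mvuTransform(model, xNew[, j], w), numeric(nrow(model@Y)))
    return(matrix(out, nrow = nrow(model@Y)))
  }
  iw <- incrementalWeights(model, xNew, w)
  drop(model@Y[, iw$indices, drop = FALSE] %*% iw$weights)
}

#' @rdname mvuTransform
#' @param XNew D x nNew matrix of new samples.
#' @export
transformBatch <- function(model, XNew, w = modelParams(model)$w)
  mvuTransform(model, as.matrix(XNew), w)

#' Persist / restore an embedding model
#'
#' Writes all model matrices as plain-text files plus a
#' \code{params.json} with the free parameters, landmark indices and
#' provenance ids.  \code{loadModel(saveModel(m))} reproduces transforms
#' bit for bit.
#'
#' @param model an \linkS4class{EmbeddingModel}.
#' @param path directory to write to / read from.
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: the model.
#' @export
saveModel <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("X", "Y", "W", "Q", "L", "eigenvectors"))
    .writeMatrixTxt(slot(model, nm), file.path(path, paste0(nm, ".txt")))
  jsonlite::write_json(
    list(params = model@params, landmarks = model@landmarks,
         trainIds = model@trainIds, eigenvalues = model@eigenvalues,
         solverStatus = model@solverStatus["gap"]),
    file.path(path, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  pj <- file.path(path, "params.json")
  if (!file.exists(pj)) stop("missing params.json in ", path)
  meta <- jsonlite::read_json(pj, simplifyVector = TRUE)
  mats <- lapply(c(X = "X", Y = "Y", W = "W", Q = "Q", L = "L",
                   eigenvectors = "eigenvectors"), function(nm) {
    f <- file.path(path, paste0(nm, ".txt"))
    if (!file.exists(f)) stop("missing model matrix file ", nm, ".txt")
    .readMatrixTxt(f)
  })
  new("EmbeddingModel", X = mats$X, Y = mats$Y, W = mats$W, Q = mats$Q,
      L = mats$L, eigenvalues = as.numeric(meta$eigenvalues),
      eigenvectors = mats$eigenvectors,
      params = lapply(as.list(meta$params), as.integer),
      landmarks = as.integer(meta$landmarks),
      trainIds = as.character(meta$trainIds),
      solverStatus = as.list(meta$solverStatus))
}
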