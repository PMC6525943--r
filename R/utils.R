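# internal helpers shared across modules

# run code with a temporary RNG seed, restoring global state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.movingAverage <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# reflection padding (no repeated edge sample): x[1-j] = x[1+j]
.reflectPad <- function(x, left, right) {
  n <- length(x)
  left <- min(left, n - 1L); right <- min(right, n - 1L)
  c(if (left > 0L) x[seq(left + 1L, 2L)] else numeric(0),
    x,
    if (right > 0L) x[seq(n - 1L, n - right)] else numeric(0))
}

.writeMatrixTxt <- function(m, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# %d %d", nrow(m), ncol(m)),
               apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))),
             con)
  close(con)
}

.readMatrixTxt <- function(path) {
  hdr <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
  nr <- as.integer(hdr[2L]); nc <- as.integer(hdr[3L])
  v <- scan(path, skip = 1L, quiet = TRUE)
  stopifnot(length(v) == nr * nc)
  matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
}

.isWholeNumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol
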