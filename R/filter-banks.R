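.firstLevelCatalogue <- c(Antonini = "antonini", LeGall = "legall",
                          Near_Sym_a = "near_sym_a", Near_Sym_b = "near_sym_b")
.laterLevelCatalogue <- c(Qshift_06 = "qshift_06", Qshift_a = "qshift_a",
                          Qshift_b = "qshift_b", Qshift_c = "qshift_c",
                          Qshift_d = "qshift_d")

.readFilterFile <- function(fname) {
  path <- system.file("extdata", "filters", fname, package = "ilmd", mustWork = TRUE)
  hdr <- scan(path, what = character(), nlines = 1L, comment.char = "", quiet = TRUE)
  .filt(scan(path, skip = 1L, quiet = TRUE), as.integer(hdr[3L]))
}

.shiftFilt <- function(f, by) .filt(f$coef, f$t0 + as.integer(by))

#' Load a dual-tree complex wavelet filter bank
#'
#' Assembles the per-tree analysis/synthesis filters for one of the
#' catalogued first-level (odd-length biorthogonal) / later-level
#' (even-length orthonormal Q-shift) combinations.  The default pairing is
#' Antonini 9,7 with the 16-tap Q-shift bank.  Tree B's first level is the
#' same filter pair delayed by one sample; its Q-shift low-pass is the time
#' reverse of tree A's, so the two low-pass chains differ by approximately
#' half a sample per level -- the property that makes the dual tree nearly
#' shift invariant.
#'
#' @param firstLevel one of \code{"Antonini"}, \code{"LeGall"},
#'   \code{"Near_Sym_a"}, \code{"Near_Sym_b"}.
#' @param laterLevel one of \code{"Qshift_06"}, \code{"Qshift_a"},
#'   \code{"Qshift_b"}, \code{"Qshift_c"}, \code{"Qshift_d"}.
#' @return a \linkS4class{FilterBank}.
#' @examples
#' fb <- loadFilterBank()
#' fb
#' @export
loadFilterBank <- function(firstLevel = "Antonini", laterLevel = "Qshift_c") {
  if (!firstLevel %in% names(.firstLevelCatalogue))
    stop("unknown first-level filter bank: ", firstLevel)
  if (!laterLevel %in% names(.laterLevelCatalogue))
    stop("unknown later-level filter bank: ", laterLevel)
  p1 <- .firstLevelCatalogue[[firstLevel]]
  lvl1a <- list(h0 = .readFilterFile(paste0(p1, "_h0.txt")),
                h1 = .readFilterFile(paste0(p1, "_h1.txt")),
                f0 = .readFilterFile(paste0(p1, "_f0.txt")),
                f1 = .readFilterFile(paste0(p1, "_f1.txt")))
  lvl1b <- lapply(lvl1a, .shiftFilt, by = 1L)
  h0a <- .readFilterFile(paste0(.laterLevelCatalogue[[laterLevel]], "_h0a.txt"))
  L <- length(h0a$coef)
  qmf <- function(h) .filt(rev(h$coef) * (-1)^(seq_len(L) - 1L), h$t0)
  h0b <- .filt(rev(h0a$coef), 0L)
  lvlqa <- list(h0 = h0a, h1 = qmf(h0a), f0 = h0a, f1 = qmf(h0a))
  lvlqb <- list(h0 = h0b, h1 = qmf(h0b), f0 = h0b, f1 = qmf(h0b))
  new("FilterBank", firstLevelName = firstLevel, laterLevelName = laterLevel,
      lvl1a = lvl1a, lvl1b = lvl1b, lvlqa = lvlqa, lvlqb = lvlqb)
}

#' Half-sample delay offset of a Q-shift pair
#'
#' Sub-sample position (parabolic interpolation) of the cross-correlation
#' peak between the tree-A and tree-B later-level low-pass filters; a
#' proper Q-shift pair gives approximately +/- 0.5 samples.
#'
#' @param fb a \linkS4class{FilterBank}.
#' @return numeric scalar, the peak offset in samples.
#' @export
halfSampleDelayOffset <- function(fb) {
  ha <- fb@lvlqa$h0$coef; hb <- fb@lvlqb$h0$coef
  cc <- .convFull(ha, rev(hb))
  k <- which.max(abs(cc))
  y <- cc[(k - 1L):(k + 1L)]
  (k - length(ha)) + 0.5 * (y[1L] - y[3L]) / (y[1L] - 2 * y[2L] + y[3L])
}
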