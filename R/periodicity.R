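## Periodicity detection in positional signals: loess detrending followed by
## a plain FFT periodogram, used to expose the 10-bp helical-pitch signature
## of fragment-end positions.

#' Detrend a positional signal by locally weighted regression
#'
#' Fits a loess smoother (degree 1, tricube weights) to the series and
#' returns the centered residuals, removing the broad nucleosomal envelope
#' so that only the fine-scale oscillation remains.
#'
#' @param signal numeric series (length >= 10).
#' @param span loess span as a fraction of the series (default 0.3).
#' @return numeric residual series with mean zero (to numerical precision).
#' @export
detrend <- function(signal, span = 0.3) {
  n <- length(signal)
  if (n < 10L) stop("signal too short to detrend (need >= 10 points)")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (span * n < 4) stop("span too small for this signal length")
  x <- seq_len(n)
  fit <- loess(signal ~ x, span = span, degree = 1,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  r <- signal - predict(fit, x)
  r - mean(r)
}

#' @importFrom stats loess.control
NULL

#' FFT periodogram of a (detrended) signal
#'
#' Squared-magnitude discrete Fourier spectrum `|X(f)|^2 / n` at the Fourier
#' frequencies `k/n`, `k = 1..floor(n/2)`, optionally zero-padded for finer
#' frequency resolution.
#'
#' @param signal numeric series, ideally detrended ([detrend()]).
#' @param pad_to optional length (> `length(signal)`) to zero-pad to.
#' @return an object of class `periodogram`: list with `freq` (cycles/bp),
#'   `spec` (density, arbitrary units), and `n` (source signal length).
#' @export
periodogram <- function(signal, pad_to = NULL) {
  n <- length(signal)
  if (n < 4L) stop("signal too short for a periodogram")
  x <- signal
  if (!is.null(pad_to)) {
    if (pad_to < n) stop("pad_to must be >= signal length")
    x <- c(x, numeric(pad_to - n))
  }
  m <- length(x)
  X <- fft(x)
  k <- seq_len(floor(m / 2))
  structure(list(freq = k / m, spec = Mod(X[k + 1L])^2 / n, n = n),
            class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  cat("<periodogram> ", length(x$freq), " frequencies from a length-",
      x$n, " signal\n", sep = "")
  invisible(x)
}

#' Dominant period within a band
#'
#' @param pg a [periodogram()].
#' @param band numeric length-2 period interval in bp (default `c(5, 20)`,
#'   bracketing the 10-bp helical pitch).
#' @return the period (bp) of maximal spectral density within the band;
#'   ties break toward the shorter period.
#' @export
dominant_period <- function(pg, band = c(5, 20)) {
  period <- 1 / pg$freq
  sel <- which(period >= band[1] & period <= band[2])
  if (length(sel) == 0L) stop("no Fourier frequency falls inside the band")
  sel <- sel[order(-pg$spec[sel], period[sel])]
  period[sel[1]]
}
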