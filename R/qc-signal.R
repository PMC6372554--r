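#' Nuisance regression of regional time series
#'
#' Ordinary-least-squares residuals of every region on an intercept plus the
#' supplied nuisance regressors (e.g. the Friston-24 motion design and a
#' global-signal regressor). Residual columns are orthogonal to every
#' regressor. Regressor columns that are constant (duplicates of the
#' intercept) are dropped silently; any remaining rank deficiency is an error
#' that names the offending columns.
#'
#' @param ts T x N numeric matrix of regional series.
#' @param regressors Optional T x K numeric matrix. `NULL` means
#'   intercept-only (column demeaning).
#' @return T x N residual matrix.
#' @export
nuisance_regress <- function(ts, regressors = NULL) {
  ts <- as.matrix(ts)
  tt <- nrow(ts)
  if (is.null(regressors)) {
    return(scale(ts, center = TRUE, scale = FALSE)[, , drop = FALSE])
  }
  x <- as.matrix(regressors)
  if (is.null(colnames(x))) colnames(x) <- paste0("reg", seq_len(ncol(x)))
  keep <- apply(x, 2, function(col) sd(col) > 0)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) + 1 >= tt) abort("more regressors than timepoints.")
  design <- cbind(`(Intercept)` = 1, x)
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    bad <- colnames(design)[qr_x$pivot[(qr_x$rank + 1):ncol(design)]]
    abort(paste0("rank-deficient nuisance design; offending columns: ",
                 paste(bad, collapse = ", ")))
  }
  res <- qr.resid(qr_x, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Linear detrend and ideal band-pass filter
#'
#' Removes a per-region least-squares linear trend, then applies an ideal
#' frequency-domain band-pass that retains Fourier bins whose frequency lies
#' in `[low_hz, high_hz]` inclusive (the conventional 0.01-0.1 Hz band for
#' resting-state series). The filter is linear and leaves each region with
#' (numerically) zero mean.
#'
#' @param ts T x N matrix.
#' @param tr_s Repetition time in seconds (sampling interval).
#' @param low_hz,high_hz Pass band in Hz; must satisfy
#'   `0 <= low < high < 1/(2 tr_s)`.
#' @return Filtered T x N matrix.
#' @export
detrend_bandpass <- function(ts, tr_s, low_hz = 0.01, high_hz = 0.1) {
  ts <- as.matrix(ts)
  tt <- nrow(ts)
  if (tt < 16) abort("need at least 16 timepoints to band-pass.")
  nyquist <- 1 / (2 * tr_s)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyquist)) {
    abort("pass band must satisfy 0 <= low < high < Nyquist.")
  }
  tvec <- seq_len(tt)
  design <- cbind(1, tvec)
  detr <- qr.resid(qr(design), ts)
  freqs <- pmin(0:(tt - 1), tt - (0:(tt - 1))) / (tt * tr_s)
  eps <- 1e-9
  keep <- freqs >= low_hz - eps & freqs <= high_hz + eps
  out <- apply(detr, 2, function(x) {
    xf <- fft(x)
    xf[!keep] <- 0i
    Re(fft(xf, inverse = TRUE)) / tt
  })
  dimnames(out) <- dimnames(ts)
  out
}
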