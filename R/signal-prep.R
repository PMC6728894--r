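#' Regress nuisance signals out of ROI time series
#'
#' Projects every region's signal onto the orthogonal complement of the
#' nuisance design (plus an intercept) and returns the least-squares
#' residuals, the ROI-level analogue of volume-wise 14-parameter nuisance
#' regression (six motion traces, their derivatives, white-matter and CSF
#' signals). Residual columns have mean zero by construction.
#'
#' @param ts An [roi_timeseries()].
#' @param nuisance T x K numeric matrix or data frame of regressors.
#' @return An [roi_timeseries()] of residuals.
#' @export
regress_nuisance <- function(ts, nuisance) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nuis <- as.matrix(nuisance)
  if (!is.numeric(nuis) || anyNA(nuis))
    stop("nuisance must be numeric with no missing values", call. = FALSE)
  if (nrow(nuis) != nrow(ts$values))
    stop(sprintf("nuisance has %d rows but the series has %d time points",
                 nrow(nuis), nrow(ts$values)), call. = FALSE)
  if (is.null(colnames(nuis)))
    colnames(nuis) <- sprintf("nuis%02d", seq_len(ncol(nuis)))
  design <- cbind(`(intercept)` = 1, nuis)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    dropped <- colnames(design)[qd$pivot[seq(qd$rank + 1, ncol(design))]]
    stop("nuisance design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qd, ts$values)
  roi_timeseries(res, subject_id = ts$subject_id,
                 tr_seconds = ts$tr_seconds,
                 region_labels = colnames(ts$values))
}

# Frequency mask for a real series of length n sampled every tr seconds:
# TRUE where the folded frequency lies in [low, high].
bandpass_mask <- function(n, tr, low_hz, high_hz) {
  fs <- 1 / tr
  f <- (seq_len(n) - 1) / (n * tr)
  folded <- pmin(f, fs - f)
  folded >= low_hz & folded <= high_hz
}

#' Temporal band-pass filter (zero-phase, frequency domain)
#'
#' Retains Fourier components with frequency inside `[low_hz, high_hz]`
#' and zeroes all others (including the DC term), the ideal rectangular
#' filter commonly used for resting-state fMRI band-limiting. The
#' operation is zero-phase and exactly linear and idempotent; measured
#' pass-band gain is 1 and stop-band gain 0 up to spectral leakage of
#' finite-length signals.
#'
#' @param ts An [roi_timeseries()].
#' @param low_hz,high_hz Band edges in Hz (defaults 0.01 and 0.08).
#' @return A filtered [roi_timeseries()].
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(ts, "roi_timeseries"))
  assert_scalar_number(low_hz, "low_hz", min = 0)
  assert_scalar_number(high_hz, "high_hz", min = 0)
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (high_hz >= nyquist)
    stop(sprintf("high_hz = %g must be below the Nyquist frequency %g Hz",
                 high_hz, nyquist), call. = FALSE)
  if (low_hz >= high_hz)
    stop("low_hz must be below high_hz", call. = FALSE)
  x <- ts$values
  n <- nrow(x)
  mask <- bandpass_mask(n, ts$tr_seconds, low_hz, high_hz)
  xf <- mvfft(x)
  xf[!mask, ] <- 0
  y <- Re(mvfft(xf, inverse = TRUE)) / n
  dimnames(y) <- dimnames(x)
  roi_timeseries(y, subject_id = ts$subject_id, tr_seconds = ts$tr_seconds,
                 region_labels = colnames(x))
}
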