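# Preprocessing: nuisance regression and temporal band-pass filtering.

# Ideal FFT band-pass of the rows of X (rows = voxels, columns = timepoints).
# The row mean is removed first; Fourier bins with f_lo < f < f_hi (two-sided)
# are retained, all others zeroed, so the output is exactly band-limited and
# has mean ~ 0.
fft_bandpass_matrix <- function(X, tr_s, f_lo, f_hi) {
  T <- ncol(X)
  X <- X - rowMeans(X)
  f <- (seq_len(T) - 1) / (T * tr_s)
  f <- pmin(f, 1 / tr_s - f)      # fold to two-sided frequency magnitude
  keep <- f > f_lo & f < f_hi
  Xf <- t(stats::mvfft(t(X)))
  Xf[, !keep] <- 0
  Re(t(stats::mvfft(t(Xf), inverse = TRUE))) / T
}

#' Band-pass filter a session image
#'
#' Applies an ideal frequency-domain band-pass filter to every voxel series:
#' the series mean is removed, Fourier bins with `f_lo < f < f_hi` are
#' retained and all others (including the DC bin) are zeroed. The default
#' band, 0.01-0.1 Hz, is the conventional low-frequency resting-state band.
#'
#' @param image A [session_image()].
#' @param f_lo,f_hi Passband edges in Hz.
#' @return A `session_image` with filtered signal (mean approximately zero
#'   per voxel).
#' @export
bandpass <- function(image, f_lo = 0.01, f_hi = 0.1) {
  stopifnot(is_session_image(image))
  nyq <- 1 / (2 * image$tr_s)
  if (!(0 < f_lo && f_lo < f_hi && f_hi < nyq))
    stop_config("band (%g, %g) Hz invalid for TR %g s (Nyquist %g Hz)",
                f_lo, f_hi, image$tr_s, nyq)
  if (ncol(image$signal) < 100)
    stop_config("band-pass requires >= 100 timepoints, got %d",
                ncol(image$signal))
  out <- image
  out$signal <- fft_bandpass_matrix(image$signal, image$tr_s, f_lo, f_hi)
  rownames(out$signal) <- rownames(image$signal)
  out
}

#' Assemble a nuisance regressor set
#'
#' @param motion Numeric matrix of six motion parameters (timepoints x 6).
#' @param csf,wm Per-timepoint mean signals of cerebrospinal fluid and white
#'   matter masks.
#' @return A data frame of nuisance regressors.
#' @export
nuisance_set <- function(motion, csf, wm) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop_config("motion matrix must have 6 columns, got %d", ncol(motion))
  if (length(csf) != nrow(motion) || length(wm) != nrow(motion))
    stop_config("csf/wm series length must match motion rows")
  out <- data.frame(motion, csf = csf, wm = wm)
  names(out)[1:6] <- paste0("motion", 1:6)
  out
}

#' Regress nuisance signals out of a session image
#'
#' Replaces every voxel series by its ordinary-least-squares residual against
#' the nuisance design. A constant and a linear trend are always included in
#' the design (detrending stabilizes the subsequent frequency-domain filter),
#' so residuals are mean-zero and orthogonal to every regressor.
#'
#' @param image A [session_image()].
#' @param nuisance Data frame or matrix of per-timepoint nuisance regressors
#'   (e.g. from [nuisance_set()]), or `NULL` for constant + trend only.
#' @return A `session_image` of residuals.
#' @export
regress_nuisance <- function(image, nuisance = NULL) {
  stopifnot(is_session_image(image))
  T <- ncol(image$signal)
  X <- cbind(intercept = 1, trend = seq_len(T) - (T + 1) / 2)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != T)
      stop_config("nuisance has %d rows but image has %d timepoints",
                  nrow(nuisance), T)
    X <- cbind(X, nuisance)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_numeric("nuisance design is rank deficient; collinear columns: %s",
                 paste(dropped, collapse = ", "))
  }
  out <- image
  out$signal <- t(qr.resid(qrX, t(image$signal)))
  rownames(out$signal) <- rownames(image$signal)
  out
}
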