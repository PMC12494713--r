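#' Generator parameters
#'
#' Bundles and validates the tunable parameters of the multi-session phantom
#' generator. Defaults are calibrated so that, on the 30-session daily
#' schedule, the population temporal drift score of a seed-ROI analysis is
#' close to -0.2, the magnitude reported for medial-temporal seeds in dense
#' sampling studies.
#'
#' The latent connectivity weights of every seed evolve across sessions as a
#' random walk in weight space: `w_s = w_{s-1} + delta * sqrt(dt) * eta` with
#' `eta` a fresh unit-norm random direction, so expected pattern similarity
#' decays monotonically with the elapsed time between two sessions whatever
#' their position in the schedule. `drift_model = "linear"` instead moves the
#' weights along a single fixed direction at rate `delta` per day.
#'
#' @param n_timepoints Timepoints per session (default 200).
#' @param tr_s Repetition time in seconds (default 0.72).
#' @param delta Per-day random-walk step size in connectivity-weight space
#'   (>= 0). Zero means no drift.
#' @param gradient_slope Relative change of `delta` per millimetre of y for
#'   hippocampal voxel seeds: `delta(v) = delta * (1 + gradient_slope *
#'   (y_v - mean(y)))`. Positive values give faster drift anteriorly (larger
#'   y), hence more negative voxel drift scores anteriorly and a negative
#'   drift-score-vs-y correlation. Every per-voxel `delta(v)` must remain
#'   >= 0.
#' @param beta_h,beta_m,beta_e Couplings of the hormone, motion and emotion
#'   covariates into the connectivity weights: each covariate drives a random
#'   walk over its own axis, so the expected squared weight displacement
#'   between two sessions is `beta^2` times the absolute covariate
#'   difference (in SD units of the covariate).
#' @param sigma Observation noise standard deviation added to every target
#'   voxel timepoint (> 0).
#' @param hpc_weight_scale Norm of each hippocampal voxel seed's latent
#'   weight vector relative to the ROI seeds' unit norm (default 1).
#' @param seed_voxel_noise Noise standard deviation added to seed voxel
#'   series on top of their latent signal (default 0.1).
#' @param latent_band Passband (Hz) of the latent signals, applied as an
#'   ideal FFT filter to white noise (default c(0.01, 0.35)).
#' @param hormone_period_days Period of the cyclic hormone series (default
#'   28).
#' @param hormone_amplitude Amplitude of the hormone cycle (default 1).
#' @param covariate_noise Noise scale shared by all covariate series
#'   (default 1). Zero together with `hormone_amplitude = 0` gives constant
#'   covariates.
#' @param loadings Loadings of the four questionnaire scores on the single
#'   latent emotion factor (default 0.9 each).
#' @param delta_overrides Optional named numeric vector overriding `delta`
#'   for specific seed labels (e.g. `c(ec_al = 0.1, ec_pm = 0)`).
#' @param drift_networks Optional character vector of network names; when
#'   given, random-walk steps are restricted to target voxels of these
#'   networks (weights elsewhere stay fixed).
#' @param drift_model `"random_walk"` (default) or `"linear"`.
#' @return A list of class `"generator_params"`.
#' @export
generator_params <- function(n_timepoints = 200L,
                             tr_s = 0.72,
                             delta = 0.315,
                             gradient_slope = 0,
                             beta_h = 0, beta_m = 0, beta_e = 0,
                             sigma = 4,
                             hpc_weight_scale = 1,
                             seed_voxel_noise = 0.1,
                             latent_band = c(0.01, 0.35),
                             hormone_period_days = 28,
                             hormone_amplitude = 1,
                             covariate_noise = 1,
                             loadings = c(0.9, 0.9, 0.9, 0.9),
                             delta_overrides = NULL,
                             drift_networks = NULL,
                             drift_model = c("random_walk", "linear")) {
  drift_model <- match.arg(drift_model)
  if (tr_s <= 0) stop_config("tr_s must be positive, got %g", tr_s)
  if (n_timepoints < 8) stop_config("n_timepoints must be >= 8")
  if (delta < 0) stop_config("delta must be >= 0, got %g", delta)
  if (sigma <= 0) stop_config("sigma must be > 0, got %g", sigma)
  if (length(latent_band) != 2L || latent_band[1] <= 0 ||
      latent_band[1] >= latent_band[2] || latent_band[2] >= 1 / (2 * tr_s))
    stop_config("latent_band must satisfy 0 < lo < hi < Nyquist = %g Hz",
                1 / (2 * tr_s))
  if (any(loadings < -1 | loadings > 1))
    stop_config("questionnaire loadings must lie in [-1, 1]")
  if (!is.null(delta_overrides) &&
      (is.null(names(delta_overrides)) || any(delta_overrides < 0)))
    stop_config("delta_overrides must be a named non-negative numeric vector")

  structure(list(
    n_timepoints = as.integer(n_timepoints), tr_s = tr_s, delta = delta,
    gradient_slope = gradient_slope,
    beta_h = beta_h, beta_m = beta_m, beta_e = beta_e,
    sigma = sigma, hpc_weight_scale = hpc_weight_scale,
    seed_voxel_noise = seed_voxel_noise, latent_band = latent_band,
    hormone_period_days = hormone_period_days,
    hormone_amplitude = hormone_amplitude,
    covariate_noise = covariate_noise, loadings = loadings,
    delta_overrides = delta_overrides, drift_networks = drift_networks,
    drift_model = drift_model
  ), class = "generator_params")
}
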