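# Multi-session phantom generator: covariate tables and session images with
# known ground-truth drift rates and covariate couplings.

#' Simulate per-session covariates
#'
#' Generates the session-level covariate table the analysis controls for:
#' four hormone series (smooth cyclic functions of elapsed time plus noise),
#' mean framewise displacement (a positive motion summary), and four
#' questionnaire scores driven by a single latent emotion factor through the
#' loadings in `params`.
#'
#' @param schedule Schedule from [make_schedule()].
#' @param params [generator_params()].
#' @param seed Optional RNG seed for reproducibility.
#' @return Data frame with one row per session: `session_id`, `t_days`,
#'   `mean_fd`, hormone columns (`estradiol`, `progesterone`, `lh`, `fsh`)
#'   and questionnaire columns (`pss`, `stai`, `pom_tension`,
#'   `pom_depression`). The latent emotion factor is attached as
#'   `attr(x, "emotion_latent")`.
#' @export
simulate_covariates <- function(schedule, params, seed = NULL) {
  if (nrow(schedule) < 1L) stop_config("schedule is empty")
  maybe_set_seed(seed)
  t <- schedule$t_days
  n <- length(t)
  amp <- params$hormone_amplitude
  nz <- params$covariate_noise

  phases <- c(estradiol = 0, progesterone = pi / 2, lh = pi, fsh = 3 * pi / 2)
  phase0 <- stats::runif(1, 0, 2 * pi)   # cycle phase at study start
  hormones <- vapply(phases, function(ph) {
    amp * sin(2 * pi * t / params$hormone_period_days + ph + phase0) +
      0.1 * nz * stats::rnorm(n)
  }, numeric(n))
  hormones <- matrix(hormones, nrow = n,
                     dimnames = list(NULL, names(phases)))

  mean_fd <- 0.12 * exp(0.25 * nz * stats::rnorm(n))

  # latent emotion factor: smooth AR(1) series, unit variance when noisy
  e_raw <- as.numeric(stats::filter(stats::rnorm(n), 0.5, "recursive"))
  e <- if (n > 1 && stats::sd(e_raw) > 0 && nz > 0)
    nz * as.numeric(scale(e_raw)) else rep(0, n)

  l <- params$loadings
  q_base <- c(pss = 16, stai = 35, pom_tension = 8, pom_depression = 8)
  q <- vapply(seq_along(l), function(j) {
    q_base[j] + 4 * (l[j] * e + nz * sqrt(max(0, 1 - l[j]^2)) * stats::rnorm(n))
  }, numeric(n))
  q <- matrix(q, nrow = n, dimnames = list(NULL, names(q_base)))

  out <- data.frame(session_id = schedule$session_id, t_days = t,
                    mean_fd = mean_fd, hormones, q,
                    stringsAsFactors = FALSE)
  attr(out, "emotion_latent") <- e
  out
}

# standardize a series; zero-variance series map to all zeros
std0 <- function(x) {
  if (length(x) > 1 && stats::sd(x) > 0) as.numeric(scale(x)) else rep(0, length(x))
}

unit_vec <- function(n) {
  v <- stats::rnorm(n)
  v / sqrt(sum(v^2))
}

# latent-unit bookkeeping: ROI seeds share one latent signal per ROI,
# hippocampal voxels get one latent each (needed for voxelwise seeding)
latent_units <- function(layout, params) {
  units <- list()
  for (lab in c("ec_al", "ec_pm", "m1", "prc")) {
    rows <- which(layout$label == lab)
    if (!length(rows)) next
    d <- unname(params$delta_overrides[lab])
    units[[length(units) + 1L]] <- list(
      name = lab, rows = rows, scale = 1,
      delta = if (length(d) && !is.na(d)) d else params$delta)
  }
  hpc_rows <- which(layout$label == "hpc")
  if (length(hpc_rows)) {
    y <- layout$y_mm[hpc_rows]
    d0 <- unname(params$delta_overrides["hpc"])
    d0 <- if (length(d0) && !is.na(d0)) d0 else params$delta
    dv <- d0 * (1 + params$gradient_slope * (y - mean(y)))
    if (any(dv < 0))
      stop_config("gradient_slope %g drives %d hippocampal voxel drift rates below 0",
                  params$gradient_slope, sum(dv < 0))
    for (k in seq_along(hpc_rows)) {
      units[[length(units) + 1L]] <- list(
        name = sprintf("hpc_v%d", layout$voxel_id[hpc_rows[k]]),
        rows = hpc_rows[k], scale = params$hpc_weight_scale, delta = dv[k])
    }
  }
  units
}

#' Simulate a multi-session phantom dataset
#'
#' Generates one session image per scheduled session plus the ground truth
#' needed for recovery tests. Each latent seed (entorhinal, control, and
#' per-hippocampal-voxel) carries a band-limited latent signal `u(t)` and a
#' latent weight vector over the gray-matter target voxels; a target voxel
#' emits the weighted sum of the latent signals plus observation noise, so
#' its empirical seed correlation recovers the weight up to scale. The
#' latent signals are mutually orthogonalized within each session, so the
#' only map noise is the observation noise and the finite scan length.
#'
#' Weights evolve across sessions as a random walk with per-day step `delta`
#' (`sqrt(dt)` scaling); hippocampal voxels drift at a rate that varies
#' linearly along the longitudinal (y) axis. Each covariate channel with a
#' nonzero `beta` contributes an independent norm-preserving (spherical)
#' random walk indexed by the sorted covariate value, mixed into the weight
#' vector with amplitude `beta`: expected pattern similarity between two
#' sessions then declines (approximately linearly) in the absolute covariate
#' difference, independently of the elapsed time.
#'
#' @param schedule Schedule from [make_schedule()].
#' @param layout Voxel table from [phantom_layout()].
#' @param params [generator_params()].
#' @param covariates Covariate table from [simulate_covariates()]; generated
#'   internally (from the current RNG stream) when `NULL`.
#' @param seed Optional RNG seed; identical inputs and seed give bit-identical
#'   output.
#' @return A list with elements `sessions` (list of [session_image()]),
#'   `covariates` (the covariate table used) and `truth` (ground truth:
#'   per-session latent weights, per-unit drift rates, coupling directions
#'   and standardized covariate series).
#' @export
simulate_sessions <- function(schedule, layout, params, covariates = NULL,
                              seed = NULL) {
  maybe_set_seed(seed)
  if (is.null(covariates))
    covariates <- simulate_covariates(schedule, params)
  stopifnot(nrow(covariates) == nrow(schedule))

  units <- latent_units(layout, params)
  if (!length(units)) stop_config("layout contains no seed ROIs")
  tgt <- which(layout$label == "gm")
  if (!length(tgt)) stop_config("layout contains no gray-matter targets")
  V <- length(tgt)
  L <- length(units)
  S <- nrow(schedule)
  nt <- params$n_timepoints
  t_days <- schedule$t_days

  # step mask for network-restricted drift
  mask <- rep(TRUE, V)
  if (!is.null(params$drift_networks)) {
    mask <- layout$network[tgt] %in% params$drift_networks
    if (!any(mask))
      stop_config("drift_networks matches no target voxels")
  }

  # standardized covariate channels
  h_std <- std0(covariates$estradiol)
  m_std <- std0(covariates$mean_fd)
  e_std <- std0(attr(covariates, "emotion_latent") %||% rep(0, S))

  # spherical (norm-preserving) random walk: a tangent step of angle theta
  # followed by renormalization. The expected inner product between two
  # positions decays as the product of cos(theta) over the steps between
  # them, so expected pattern similarity is a pure function of the
  # accumulated step sizes -- no dependence on where in the walk a session
  # sits. Time uses steps delta*sqrt(dt); a covariate channel walks along
  # its sorted covariate axis with steps sqrt(|dc|), making the expected
  # similarity decline ~linear in the absolute covariate difference (the
  # regressor the confound-controlled regression uses).
  sph_step <- function(w, theta, masked = FALSE) {
    if (theta == 0) return(w)
    g <- stats::rnorm(V)
    if (masked) g[!mask] <- 0
    g <- g - sum(g * w) * w
    ng <- sqrt(sum(g^2))
    if (ng == 0) return(w)
    cos(theta) * w + sin(theta) * (g / ng)
  }
  # time drift: Euclidean random walk with sqrt(dt) steps, so similarity
  # decays monotonically in elapsed time for every pair
  time_walk <- function(delta) {
    W <- matrix(0, V, S)
    w <- unit_vec(V)
    W[, 1] <- w
    for (s in seq_len(S)[-1]) {
      w <- w + delta * sqrt(t_days[s] - t_days[s - 1]) * masked_unit()
      W[, s] <- w
    }
    W
  }
  covariate_walk <- function(series) {
    W <- matrix(0, V, S)
    ord <- order(series)
    w <- unit_vec(V)
    W[, ord[1]] <- w
    for (k in seq_len(S)[-1]) {
      w <- sph_step(w, sqrt(series[ord[k]] - series[ord[k - 1]]))
      W[, ord[k]] <- w
    }
    W
  }

  masked_unit <- function() {
    v <- stats::rnorm(V)
    v[!mask] <- 0
    v / sqrt(sum(v^2))
  }

  # latent weight trajectories: per unit, a unit-norm time walk mixed with
  # one unit-norm walk per active covariate channel, the mixture normalized
  # so every session's weight vector has norm u$scale
  betas <- c(h = params$beta_h, m = params$beta_m, e = params$beta_e)
  cov_series <- list(h = h_std, m = m_std, e = e_std)
  weights <- vector("list", L)
  names(weights) <- vapply(units, `[[`, "", "name")
  for (li in seq_len(L)) {
    u <- units[[li]]
    W <- if (params$drift_model == "random_walk") {
      time_walk(u$delta)
    } else {
      # linear drift: move along a fixed direction at delta per day
      w1 <- unit_vec(V)
      dir <- masked_unit()
      vapply(seq_len(S),
             function(s) w1 + u$delta * t_days[s] * dir, numeric(V))
    }
    for (k in names(betas)[betas > 0])
      W <- W + betas[[k]] * covariate_walk(cov_series[[k]])
    W <- W * (u$scale / sqrt(1 + sum(betas[betas > 0]^2)))
    weights[[li]] <- W
  }

  # emit session signals
  sessions <- vector("list", S)
  for (s in seq_len(S)) {
    U <- matrix(stats::rnorm(L * nt), L, nt)
    U <- fft_bandpass_matrix(U, params$tr_s, params$latent_band[1],
                             params$latent_band[2])
    # orthonormalize the latent signals within the session (they stay
    # band-limited and zero-mean): cross-talk between latent sources would
    # otherwise act as coherent session-level map noise
    U <- t(qr.Q(qr(t(U)))) * sqrt(nt)
    sdu <- apply(U, 1, stats::sd)
    U <- U / ifelse(sdu > 0, sdu, 1)

    sig <- matrix(0, nrow(layout), nt)
    Wmat <- vapply(weights, function(W) W[, s], numeric(V))  # V x L
    sig[tgt, ] <- Wmat %*% U + params$sigma *
      matrix(stats::rnorm(V * nt), V, nt)
    for (li in seq_len(L)) {
      rows <- units[[li]]$rows
      sig[rows, ] <- matrix(U[li, ], length(rows), nt, byrow = TRUE) +
        params$seed_voxel_noise *
          matrix(stats::rnorm(length(rows) * nt), length(rows), nt)
    }
    sessions[[s]] <- session_image(sig, layout, params$tr_s,
                                   session_id = schedule$session_id[s])
  }

  truth <- list(
    weights = weights,
    units = data.frame(
      name = names(weights),
      label = vapply(units, function(u) layout$label[u$rows[1]], ""),
      delta = vapply(units, `[[`, 0, "delta"),
      scale = vapply(units, `[[`, 0, "scale"),
      stringsAsFactors = FALSE),
    target_voxel_ids = layout$voxel_id[tgt],
    couplings = c(beta_h = params$beta_h, beta_m = params$beta_m,
                  beta_e = params$beta_e),
    covariate_series = data.frame(hormone = h_std, motion = m_std,
                                  emotion = e_std)
  )
  list(sessions = sessions, covariates = covariates, truth = truth)
}
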