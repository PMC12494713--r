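test_that("generator output is bit-identical for identical seeds", {
  a <- tiny_sim(seed = 11)
  b <- tiny_sim(seed = 11)
  expect_identical(a$sim$covariates, b$sim$covariates)
  expect_identical(a$sim$truth$weights, b$sim$truth$weights)
  for (s in seq_along(a$sim$sessions))
    expect_identical(a$sim$sessions[[s]]$signal, b$sim$sessions[[s]]$signal)
  c <- tiny_sim(seed = 12)
  expect_false(identical(a$sim$sessions[[1]]$signal, c$sim$sessions[[1]]$signal))
})

test_that("zero noise and zero cycle amplitude give constant covariates", {
  sch <- make_schedule("female30")
  p <- generator_params(hormone_amplitude = 0, covariate_noise = 0)
  cv <- simulate_covariates(sch, p, seed = 4)
  for (cl in setdiff(names(cv), c("session_id", "t_days")))
    expect_equal(diff(range(cv[[cl]])), 0)
})

test_that("hormone series carries its cycle period", {
  # 28-day cycle on the 30-day daily design: autocorrelation at a full lag
  # beats the half-cycle lag on average
  sch <- make_schedule("female30")
  p <- generator_params()
  acfs <- vapply(1:100, function(i) {
    h <- simulate_covariates(sch, p, seed = i)$estradiol
    a <- stats::acf(h, lag.max = 28, plot = FALSE)$acf
    c(a[15], a[29])   # lags 14 and 28
  }, numeric(2))
  expect_gt(mean(acfs[2, ]), mean(acfs[1, ]))
})

test_that("questionnaires share one latent factor with the stated loadings", {
  sch <- make_schedule("female30")
  p <- generator_params()
  cors <- rowMeans(vapply(1:50, function(i) {
    cv <- simulate_covariates(sch, p, seed = i)
    e <- attr(cv, "emotion_latent")
    vapply(c("pss", "stai", "pom_tension", "pom_depression"),
           function(q) cor(cv[[q]], e), numeric(1))
  }, numeric(4)))
  # loading 0.9 on the factor, noise sd sqrt(1 - 0.9^2)
  expect_true(all(abs(cors - 0.9) < 0.06))
})

test_that("hippocampal drift rates follow the longitudinal gradient", {
  lay <- phantom_layout()
  p <- generator_params(gradient_slope = 0.03)
  sim <- simulate_sessions(tiny_schedule(4), lay, p, seed = 2)
  units <- sim$truth$units
  hpc <- units[units$label == "hpc", ]
  y <- lay$y_mm[lay$label == "hpc"]
  expect_equal(hpc$delta, p$delta * (1 + 0.03 * (y - mean(y))))
  # steeper slope drives some delta(v) negative -> configuration error
  expect_error(
    simulate_sessions(tiny_schedule(4), lay,
                      generator_params(gradient_slope = 0.2), seed = 2),
    class = "restdrift_config_error")
})

test_that("pattern similarity declines monotonically across time bins", {
  sch <- tiny_schedule(12)
  lay <- phantom_layout(n_per_network = 6, hpc_n = 10, roi_n = 2)
  spec <- seed_spec("ec_al", label = "ec_al")
  p <- generator_params(n_timepoints = 150, delta = 0.6, sigma = 0.3)
  bins <- c(0, 3, 6, 9, 12)
  means <- rowMeans(vapply(1:10, function(i) {
    sim <- simulate_sessions(sch, lay, p, seed = 100 + i)
    pr <- pairwise_similarity(connectivity_stack(sim$sessions, spec), sch)
    as.numeric(tapply(pr$z_similarity, cut(pr$delta_t, bins), mean))
  }, numeric(4)))
  expect_true(all(diff(means) < 0))
})

test_that("low-noise connectivity maps recover the latent weights", {
  sch <- tiny_schedule(6)
  lay <- phantom_layout(n_per_network = 6, hpc_n = 10, roi_n = 2)
  p <- generator_params(n_timepoints = 200, delta = 0.2, sigma = 0.1)
  sim <- simulate_sessions(sch, lay, p, seed = 3)
  spec <- seed_spec("ec_al", label = "ec_al")
  for (s in seq_along(sim$sessions)) {
    m <- connectivity_map(sim$sessions[[s]], spec)
    expect_gt(cor(m$z, sim$truth$weights[["ec_al"]][, s]), 0.9)
  }
})

test_that("covariate channel moves similarity without mimicking time drift", {
  # delta = 0, beta_h > 0: similarity tracks |hormone difference|; the
  # partial association of similarity with elapsed time given |delta
  # hormone| is centered on zero
  sch <- make_schedule("female30")
  lay <- phantom_layout(n_per_network = 4, hpc_n = 10, roi_n = 2)
  spec <- seed_spec("ec_al", label = "ec_al")
  p <- generator_params(delta = 0, beta_h = 1, sigma = 1.1)
  stats <- vapply(1:30, function(i) {
    sim <- simulate_sessions(sch, lay, p, seed = 400 + i)
    pr <- pairwise_similarity(connectivity_stack(sim$sessions, spec), sch)
    pr <- pair_covariate_deltas(pr, sim$covariates, columns = "estradiol")
    fit <- summary(lm(z_similarity ~ delta_estradiol + delta_t, data = pr))
    c(h = fit$coefficients["delta_estradiol", "t value"],
      t = fit$coefficients["delta_t", "t value"])
  }, numeric(2))
  expect_lt(mean(stats["h", ]), -2)          # hormone channel clearly present
  expect_lt(abs(mean(stats["t", ])), 0.75)   # time association centered on 0
})
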