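test_that("emotion PCA reduces to standardization for degenerate inputs", {
  x <- c(3, 1, 4, 1, 5, 9)
  one <- emotion_pca(data.frame(pss = x))
  expect_equal(one$scores, as.numeric(scale(x)), tolerance = 1e-12)
  expect_equal(unname(one$lambda), 100)
  # two perfectly correlated variables load equally and are fully captured
  two <- emotion_pca(data.frame(a = x, b = 2 * x + 5))
  expect_equal(unname(two$lambda), c(100, 100), tolerance = 1e-10)
  expect_equal(two$loadings[["a"]], two$loadings[["b"]], tolerance = 1e-12)
  expect_equal(mean(two$scores), 0, tolerance = 1e-12)
})

test_that("emotion PCA matches an independent eigendecomposition", {
  set.seed(50)
  e <- rnorm(40)
  Q <- data.frame(pss = 0.9 * e + 0.4 * rnorm(40),
                  stai = 0.8 * e + 0.5 * rnorm(40),
                  pom_t = 0.7 * e + 0.6 * rnorm(40),
                  pom_d = -0.5 * e + 0.8 * rnorm(40))
  res <- emotion_pca(Q)
  pc <- prcomp(Q, center = TRUE, scale. = TRUE)
  load_orc <- pc$rotation[, 1] * pc$sdev[1]
  if (load_orc[1] < 0) load_orc <- -load_orc
  expect_equal(unname(res$lambda), unname(100 * load_orc^2),
               tolerance = 1e-10)
  expect_equal(abs(cor(res$scores, pc$x[, 1])), 1, tolerance = 1e-10)
  # eigenvalue ordering: PC1 captures the most variance
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_gte(res$eigenvalues[1], max(res$eigenvalues))

  expect_error(emotion_pca(data.frame(a = rep(1, 10), b = rnorm(10))),
               class = "restdrift_config_error")
  Qna <- Q; Qna$pss[3] <- NA
  expect_error(emotion_pca(Qna), class = "restdrift_config_error")
})

test_that("pair covariate deltas are absolute and order free", {
  pr <- make_pairs(1:3, rnorm(3))
  cov <- data.frame(session_id = c(pr$session_i, pr$session_j),
                    horm = c(3, 1, 2, 7, 1, 2),
                    fd = rep(0.1, 6))
  out <- pair_covariate_deltas(pr, cov, columns = c("horm", "fd"))
  expect_equal(out$delta_horm, c(4, 0, 0))
  expect_equal(out$delta_fd, rep(0, 3))
  cov_swapped <- cov
  cov_swapped$horm <- c(7, 1, 2, 3, 1, 2)
  expect_equal(pair_covariate_deltas(pr, cov_swapped, "horm")$delta_horm[1], 4)
  expect_error(pair_covariate_deltas(pr, cov[-1, ], "horm"),
               class = "restdrift_config_error")
})

test_that("drift regression matches the normal-equation oracle", {
  # exact linear time effect, no covariates (perfect fit warns in summary)
  pr <- make_pairs(1:10, 2 - 0.01 * (1:10))
  reg <- suppressWarnings(drift_regression(pr, predictors = "delta_t"))
  expect_equal(reg$B[reg$term == "delta_t"], -0.01, tolerance = 1e-10)
  expect_lt(reg$SE[reg$term == "delta_t"], 1e-10)

  # 8-pair toy design against explicit least squares
  set.seed(51)
  dt <- c(1, 2, 4, 7, 11, 16, 22, 29)
  dh <- runif(8)
  z <- 1 - 0.02 * dt - 0.3 * dh + rnorm(8, 0, 0.05)
  pr2 <- make_pairs(dt, z)
  pr2$delta_h <- dh
  reg2 <- drift_regression(pr2, predictors = c("delta_t", "delta_h"))
  X <- cbind(1, dt, dh)
  beta <- solve(t(X) %*% X, t(X) %*% z)
  resid <- z - X %*% beta
  s2 <- sum(resid^2) / (8 - 3)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(reg2$B, as.numeric(beta), tolerance = 1e-10)
  expect_equal(reg2$SE, unname(se), tolerance = 1e-10)
  expect_equal(reg2$t, reg2$B / reg2$SE, tolerance = 1e-12)
  expect_equal(reg2$p, 2 * pt(-abs(reg2$t), df = 5), tolerance = 1e-12)
  expect_equal(attr(reg2, "n"), 8L)
})

test_that("time-only regression agrees with the drift score algebra", {
  set.seed(52)
  dt <- runif(50, 1, 29)
  z <- 0.5 - 0.01 * dt + rnorm(50, 0, 0.03)
  pr <- make_pairs(dt, z)
  reg <- drift_regression(pr, predictors = "delta_t")
  r <- drift_score(pr)$r
  expect_equal(reg$B[reg$term == "delta_t"], r * sd(z) / sd(dt),
               tolerance = 1e-10)
})

test_that("collinear predictors are reported by name", {
  pr <- make_pairs(1:12, rnorm(12))
  pr$delta_dup <- 2 * pr$delta_t
  err <- tryCatch(drift_regression(pr, predictors = c("delta_t", "delta_dup")),
                  error = identity)
  expect_s3_class(err, "restdrift_numerical_error")
  expect_match(conditionMessage(err), "delta_dup")
  expect_error(drift_regression(make_pairs(1:2, rnorm(2)),
                                predictors = "delta_t"),
               class = "restdrift_analysis_error")
})

test_that("dependent-correlation z matches the published formula", {
  # equal drift scores -> no difference
  eq <- compare_dependent_correlations(-0.2, -0.2, 0.4, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 0.5)

  # independently coded oracle for the overlapping-variable z test
  meng_oracle <- function(r_jk, r_jh, r_kh, n) {
    rb2 <- (r_jk^2 + r_jh^2) / 2
    f <- min((1 - r_kh) / (2 * (1 - rb2)), 1)
    h <- (1 - f * rb2) / (1 - rb2)
    (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 * (1 - r_kh) * h))
  }
  res <- compare_dependent_correlations(-0.30, -0.10, 0.50, 200)
  expect_equal(res$z, meng_oracle(-0.30, -0.10, 0.50, 200),
               tolerance = 1e-8)
  expect_equal(res$p, pnorm(res$z), tolerance = 1e-12)

  # antisymmetry under swapping the two seeds
  swap <- compare_dependent_correlations(-0.10, -0.30, 0.50, 200)
  expect_equal(swap$z, -res$z, tolerance = 1e-12)

  expect_error(compare_dependent_correlations(-0.3, -0.1, 0.5, 3),
               class = "restdrift_domain_error")
  expect_error(compare_dependent_correlations(-1, -0.1, 0.5, 50),
               class = "restdrift_domain_error")
})

test_that("seed-vs-seed comparison uses shared included pairs", {
  set.seed(53)
  dt <- runif(40, 1, 29)
  za <- 1 - 0.02 * dt + rnorm(40, 0, 0.05)
  zb <- 1 - 0.005 * dt + rnorm(40, 0, 0.05)
  pa <- make_pairs(dt, za)
  pb <- make_pairs(dt, zb)
  pa$included[1:5] <- FALSE    # drop some pairs from seed A only
  res <- compare_seed_drifts(pa, pb)
  keep <- 6:40
  expect_equal(res$n, 35L)
  expect_equal(res$r_jk, cor(dt[keep], za[keep]), tolerance = 1e-12)
  expect_equal(res$r_kh, cor(za[keep], zb[keep]), tolerance = 1e-12)
  expect_lt(res$z, 0)   # seed A drifts more steeply
})
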