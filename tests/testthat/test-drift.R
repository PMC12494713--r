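test_that("pair enumeration covers every unordered session pair", {
  set.seed(20)
  sch <- make_schedule("female30")
  Z <- matrix(rnorm(50 * 30), 50, 30)
  pr <- pairwise_similarity(Z, sch)
  expect_equal(nrow(pr), choose(30, 2))   # 435
  expect_true(all(pr$delta_t > 0))
  expect_equal(nrow(pairwise_similarity(matrix(rnorm(50 * 40), 50, 40),
                                        make_schedule("male40"))),
               choose(40, 2))             # 780
  # identical maps -> clipped maximum; exactly decorrelated maps -> 0
  Z2 <- Z
  Z2[, 2] <- Z[, 1]
  pr2 <- pairwise_similarity(Z2, sch)
  expect_equal(pr2$z_similarity[1], atanh(1 - 1e-7))
  x <- rnorm(50)
  y <- rnorm(50)
  y <- residuals(lm(y ~ x))               # sample correlation exactly 0
  pr3 <- pairwise_similarity(cbind(x, y, Z[, 1:28]), sch)
  expect_equal(pr3$z_similarity[1], 0, tolerance = 1e-12)
})

test_that("the 3-SD rule excludes exactly the constructed outlier", {
  # nineteen mildly spread values plus one far point; by the hand-computed
  # mean and SD of the full set, only the far point exceeds 3 SDs
  z <- c(seq(0.4, 0.6, length.out = 19), 5)
  dev <- abs(z - mean(z)) / sd(z)
  expect_equal(which(dev > 3), 20L)
  flagged <- exclude_outliers(make_pairs(seq_along(z), z), k_sd = 3)
  expect_equal(sum(!flagged$included), 1L)
  expect_false(flagged$included[20])

  expect_warning(ex <- exclude_outliers(make_pairs(1:5, rep(1, 5))),
                 "zero variance")
  expect_true(all(ex$included))
})

test_that("drift score equals the covariance-formula oracle", {
  # exact linear relation
  pr <- make_pairs(1:10, 1 - 0.01 * (1:10))
  expect_equal(drift_score(pr)$r, -1)
  # toy pairs against the hand-rolled formula
  dt <- c(1, 4, 2, 9, 6)
  z <- c(0.8, 0.3, 0.6, 0.1, 0.4)
  res <- drift_score(make_pairs(dt, z))
  expect_equal(res$r, cor_oracle(dt, z), tolerance = 1e-12)
  expect_equal(res$p_parametric,
               cor.test(dt, z)$p.value, tolerance = 1e-12)
  # 1000 random instances
  set.seed(30)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    dt <- runif(n, 0, 30)
    z <- rnorm(n)
    expect_equal(drift_score(make_pairs(dt, z))$r, cor_oracle(dt, z),
                 tolerance = 1e-12)
  }
  expect_error(drift_score(make_pairs(1:5, rep(1, 5))),
               class = "restdrift_analysis_error")
  expect_error(drift_score(make_pairs(rep(2, 5), rnorm(5))),
               class = "restdrift_analysis_error")
})

test_that("excluded pairs do not enter the drift score", {
  dt <- c(1:9, 50)
  z <- c(0.5 - 0.01 * (1:9), 5)
  pr <- make_pairs(dt, z, included = c(rep(TRUE, 9), FALSE))
  expect_equal(drift_score(pr)$r, cor_oracle(dt[1:9], z[1:9]),
               tolerance = 1e-12)
  expect_equal(drift_score(pr)$n_pairs, 9L)
})

test_that("permutation p follows the add-one counting rule", {
  set.seed(31)
  pr <- make_pairs(runif(30, 0, 29), rnorm(30))
  res <- permutation_test(pr, n_shuffles = 199, seed = 7)
  expect_equal(res$p_permutation,
               (1 + sum(res$null <= res$r)) / 200)
  expect_gt(res$p_permutation, 0)
  expect_lte(res$p_permutation, 1)
  expect_equal(length(res$null), 199L)
  # reproducible under the same seed
  res2 <- permutation_test(pr, n_shuffles = 199, seed = 7)
  expect_identical(res$null, res2$null)
  # a score below every null draw sits at the floor 1/(n+1)
  pr2 <- make_pairs(1:20, 10 - (1:20) + rnorm(20, 0, 1e-4))
  res3 <- permutation_test(pr2, n_shuffles = 500, seed = 8)
  expect_equal(res3$p_permutation, 1 / 501)
})

test_that("small-sample permutation p matches full enumeration", {
  dt <- c(1, 3, 6, 10, 15, 21)
  set.seed(32)
  z <- c(0.9, 0.8, 0.75, 0.6, 0.65, 0.5)
  obs <- cor_oracle(dt, z)
  perms <- all_perms(6)
  null_exact <- apply(perms, 1, function(p) cor_oracle(dt[p], z))
  p_exact <- mean(null_exact <= obs)
  res <- permutation_test(make_pairs(dt, z), n_shuffles = 4000, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_permutation - p_exact), 1.96 * se + 1 / 4001)
})

test_that("drift score ignores linear rescaling of elapsed time", {
  set.seed(33)
  dt <- runif(40, 0.5, 29)
  z <- 0.5 - 0.01 * dt + rnorm(40, 0, 0.05)
  a <- permutation_test(make_pairs(dt, z), n_shuffles = 300, seed = 2)
  b <- permutation_test(make_pairs(dt * 24, z), n_shuffles = 300, seed = 2)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$p_permutation, b$p_permutation)
})

test_that("drift scores on shuffled pair data concentrate near zero", {
  set.seed(34)
  sch <- make_schedule("female30")
  dt <- pairwise_similarity(matrix(rnorm(10 * 30), 10, 30), sch)$delta_t
  small <- vapply(1:100, function(i)
    abs(drift_score(make_pairs(dt, rnorm(435)))$r) < 0.1, logical(1))
  expect_gte(mean(small), 0.95)
})
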