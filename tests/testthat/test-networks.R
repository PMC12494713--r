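test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(60)
  for (i in 1:1000) {
    p <- runif(sample(1:25, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), class = "restdrift_domain_error")
  expect_error(bh_fdr(c(0.1, -0.01)), class = "restdrift_domain_error")
})

test_that("a single all-voxel network reproduces the whole-brain score", {
  sch <- tiny_schedule(10)
  lay <- phantom_layout(n_per_network = 2, hpc_n = 10, roi_n = 2)
  sim <- simulate_sessions(sch, lay, tiny_params(), seed = 61)
  # relabel every gray-matter voxel into one network
  sessions <- lapply(sim$sessions, function(img) {
    img$voxels$network[img$voxels$label == "gm"] <- "All"
    img
  })
  spec <- seed_spec("ec_al", label = "ec_al")
  nd <- network_drift(sessions, sch, spec, n_shuffles = 0)
  wb <- drift_analysis(sim$sessions, sch, spec, n_shuffles = 0)
  expect_equal(nrow(nd$table), 1L)
  expect_equal(nd$table$r, wb$result$r, tolerance = 1e-12)
  expect_equal(nd$table$p_fdr, nd$table$p_parametric)
})

test_that("tiny networks are rejected by name", {
  sch <- tiny_schedule(6)
  lay <- phantom_layout(n_per_network = 2, hpc_n = 10, roi_n = 2)
  sim <- simulate_sessions(sch, lay, tiny_params(), seed = 62)
  err <- tryCatch(
    network_drift(sim$sessions, sch, seed_spec("ec_al", label = "ec_al"),
                  n_shuffles = 0, min_voxels = 10),
    error = identity)
  expect_s3_class(err, "restdrift_config_error")
  expect_match(conditionMessage(err), "VisualA")
})

test_that("drift restricted to one network stays in that network", {
  sch <- make_schedule("custom", t_days = seq(0, 29, by = 2))
  lay <- phantom_layout(n_per_network = 12, hpc_n = 10, roi_n = 2)
  p <- generator_params(delta = 0.6, drift_networks = "VisualA",
                        n_timepoints = 150, sigma = 2)
  scores <- rowMeans(vapply(1:6, function(i) {
    sim <- simulate_sessions(sch, lay, p, seed = 700 + i)
    nd <- network_drift(sim$sessions, sch,
                        seed_spec("ec_al", label = "ec_al"), n_shuffles = 0)
    stats::setNames(nd$table$r, nd$table$network)
  }, numeric(17)))
  expect_lt(scores[["VisualA"]], -0.3)
  expect_true(all(abs(scores[setdiff(names(scores), "VisualA")]) < 0.15))
})

test_that("Kruskal-Wallis H matches the tie-corrected rank formula", {
  kw_oracle <- function(values, groups) {
    n <- length(values)
    r <- rank(values)
    groups <- factor(groups)
    H <- 12 / (n * (n + 1)) *
      sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) -
      3 * (n + 1)
    ties <- table(values)
    H / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  set.seed(63)
  # two-subject network pair data with a common drift structure
  mk_subject <- function(seed) {
    set.seed(seed)
    dt <- pairwise_similarity(matrix(rnorm(8 * 10), 8, 10),
                              tiny_schedule(10))$delta_t
    z <- matrix(rnorm(45 * 5), 45, 5,
                dimnames = list(NULL, paste0("net", 1:5)))
    z[, 1] <- z[, 1] - 0.05 * dt
    list(delta_t = dt, z = z,
         included = matrix(TRUE, 45, 5,
                           dimnames = list(NULL, paste0("net", 1:5))))
  }
  subjects <- list(f = mk_subject(1), m = mk_subject(2))
  res <- kruskal_wallis_perm(subjects, n_perm = 300, seed = 64)
  # observed H equals the rank-formula oracle on the observed scores
  groups <- rep(colnames(res$scores), each = 2)
  expect_equal(res$H, kw_oracle(as.vector(res$scores), groups),
               tolerance = 1e-10)
  expect_gt(res$p, 0)
  expect_lte(res$p, 1)
  expect_equal(dim(res$scores), c(2L, 5L))
  # deterministic under a fixed seed
  res2 <- kruskal_wallis_perm(subjects, n_perm = 300, seed = 64)
  expect_identical(res$null, res2$null)

  # identical observations in every group give H = 0, p = 1
  same <- suppressWarnings(kruskal_wallis_perm(list(
    a = list(delta_t = 1:6,
             z = matrix(rep(c(1, 2, 3, 4, 5, 6), 3), 6, 3,
                        dimnames = list(NULL, paste0("n", 1:3))),
             included = matrix(TRUE, 6, 3))), n_perm = 50, seed = 1))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
})

test_that("three-group toy data reproduce the textbook H", {
  # classic small example with ties, checked against kruskal.test and the
  # explicit rank formula through the same oracle
  vals <- c(27, 2, 4, 18, 7, 9, 1, 5, 7, 16, 10, 4)
  grp <- rep(c("a", "b", "c"), each = 4)
  H_ref <- unname(kruskal.test(vals, factor(grp))$statistic)
  r <- rank(vals)
  n <- length(vals)
  H_hand <- 12 / (n * (n + 1)) *
    sum(tapply(r, grp, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(vals)
  H_hand <- H_hand / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(H_hand, H_ref, tolerance = 1e-10)
})
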