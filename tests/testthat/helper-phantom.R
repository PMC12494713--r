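# Shared fixtures: small, fast phantoms for unit tests. Acceptance-scale
# simulations live in test-acceptance.R.

tiny_schedule <- function(n = 8) make_schedule("custom", t_days = 0:(n - 1))

tiny_params <- function(...) generator_params(n_timepoints = 120, ...)

tiny_sim <- function(seed = 1, n_sessions = 8, ...) {
  sch <- tiny_schedule(n_sessions)
  lay <- phantom_layout(n_per_network = 2, hpc_n = 10, roi_n = 2)
  sim <- simulate_sessions(sch, lay, tiny_params(...), seed = seed)
  list(schedule = sch, layout = lay, sim = sim)
}

# hand-rolled Pearson correlation from the covariance formula, used as an
# independent oracle for drift_score
cor_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}

# all n! permutations of 1..n, one per row (for exact enumeration oracles)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# build a pair table directly (bypassing connectivity) for statistic tests
make_pairs <- function(delta_t, z, included = TRUE) {
  n <- length(delta_t)
  out <- data.frame(
    session_i = sprintf("s%03d_a", seq_len(n)),
    session_j = sprintf("s%03d_b", seq_len(n)),
    delta_t = delta_t, z_similarity = z,
    included = rep_len(included, n), stringsAsFactors = FALSE)
  class(out) <- c("pair_table", "data.frame")
  out
}
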