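# The core statistic: session-pair pattern similarity, 3-SD outlier
# exclusion, the temporal drift score, and its permutation null.

#' Between-session pattern similarity
#'
#' For every unordered pair of sessions, the Pearson correlation between the
#' two sessions' connectivity maps (over the common target voxels), Fisher-Z
#' transformed, together with the elapsed time between the sessions.
#'
#' @param zmat Targets-by-sessions matrix of Fisher-Z connectivity values
#'   (e.g. from [connectivity_stack()]), or a list of [connectivity_map()]
#'   data frames with identical target sets.
#' @param schedule Schedule matching the columns of `zmat`.
#' @return Data frame of class `"pair_table"`: `session_i`, `session_j`
#'   (`i < j`), `delta_t` (days), `z_similarity`, `included` (all `TRUE`;
#'   see [exclude_outliers()]).
#' @export
pairwise_similarity <- function(zmat, schedule) {
  if (is.list(zmat) && !is.matrix(zmat)) {
    ids <- lapply(zmat, function(m) m$voxel_id)
    if (!all(vapply(ids, identical, TRUE, ids[[1]])))
      stop_analysis("connectivity maps have mismatched target sets")
    zmat <- vapply(zmat, function(m) m$z, numeric(nrow(zmat[[1]])))
  }
  S <- ncol(zmat)
  if (S < 3L) stop_analysis("need >= 3 sessions, got %d", S)
  if (S != nrow(schedule))
    stop_analysis("zmat has %d sessions but schedule has %d rows", S,
                  nrow(schedule))
  if (anyDuplicated(schedule$t_days))
    stop_analysis("schedule contains sessions with identical timestamps")

  C <- stats::cor(zmat)
  ij <- which(upper.tri(C), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  i <- ij[, "row"]; j <- ij[, "col"]
  out <- data.frame(
    session_i = schedule$session_id[i],
    session_j = schedule$session_id[j],
    delta_t = schedule$t_days[j] - schedule$t_days[i],
    z_similarity = fisher_z(C[ij]),
    included = TRUE,
    stringsAsFactors = FALSE)
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Flag outlier session pairs
#'
#' Marks pairs whose similarity deviates from the mean over all pairs by
#' more than `k_sd` standard deviations (single pass; mean and SD are
#' computed once over all pairs, not re-iterated after exclusion).
#'
#' @param pairs A pair table from [pairwise_similarity()].
#' @param k_sd Standard-deviation multiplier (default 3).
#' @return The pair table with the `included` flag updated.
#' @export
exclude_outliers <- function(pairs, k_sd = 3) {
  if (k_sd <= 0) stop_config("k_sd must be positive")
  if (nrow(pairs) < 3L) stop_analysis("need >= 3 pairs")
  z <- pairs$z_similarity
  s <- stats::sd(z)
  if (s == 0) {
    warning("pair similarities have zero variance; no outliers excluded",
            call. = FALSE)
    pairs$included <- TRUE
    return(pairs)
  }
  pairs$included <- abs(z - mean(z)) <= k_sd * s
  pairs
}

#' Temporal drift score
#'
#' The Pearson correlation, over included session pairs, between pattern
#' similarity and the elapsed time between the sessions. Negative scores
#' mean connectivity patterns grow more dissimilar with time. The parametric
#' p-value is the standard two-tailed t test of the correlation with
#' `n_pairs - 2` degrees of freedom.
#'
#' @param pairs A pair table (only rows with `included == TRUE` are used).
#' @return A list of class `"drift_result"`: `r`, `p_parametric`, `n_pairs`.
#' @export
drift_score <- function(pairs) {
  use <- pairs[pairs$included, , drop = FALSE]
  n <- nrow(use)
  if (n < 3L) stop_analysis("need >= 3 included pairs, got %d", n)
  if (stats::sd(use$delta_t) == 0 || stats::sd(use$z_similarity) == 0)
    stop_analysis("zero variance in delta_t or z_similarity")
  ct <- stats::cor.test(use$delta_t, use$z_similarity, method = "pearson")
  structure(list(r = unname(ct$estimate), p_parametric = ct$p.value,
                 n_pairs = n),
            class = "drift_result")
}

#' @export
print.drift_result <- function(x, ...) {
  cat(sprintf("Temporal drift score: r = %.3f (n = %d pairs)\n", x$r,
              x$n_pairs))
  cat(sprintf("  parametric two-tailed p = %.4g\n", x$p_parametric))
  if (!is.null(x$p_permutation))
    cat(sprintf("  permutation one-tailed p = %.4g (%d shuffles)\n",
                x$p_permutation, length(x$null)))
  invisible(x)
}

#' Permutation test of a temporal drift score
#'
#' Builds the null distribution by shuffling the elapsed-time labels across
#' included session pairs (similarities fixed) and recomputing the drift
#' score, then compares the observed score against the null in the lower
#' tail (the directional hypothesis: patterns become *less* similar with
#' time). The add-one rule keeps the p-value strictly positive:
#' `p = (1 + #(null <= observed)) / (1 + n_shuffles)`.
#'
#' @param pairs A pair table.
#' @param n_shuffles Number of label shuffles (default 5000).
#' @param seed Optional RNG seed.
#' @param tail `"lower"` (default) or `"upper"`.
#' @return A `"drift_result"` with `p_permutation` and the `null` vector
#'   added.
#' @export
permutation_test <- function(pairs, n_shuffles = 5000L, seed = NULL,
                             tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (n_shuffles < 1L) stop_config("n_shuffles must be >= 1")
  res <- drift_score(pairs)
  use <- pairs[pairs$included, , drop = FALSE]
  maybe_set_seed(seed)

  n <- nrow(use)
  dt <- use$delta_t
  zc <- use$z_similarity - mean(use$z_similarity)
  denom <- (n - 1) * stats::sd(dt) * stats::sd(use$z_similarity)
  dtc <- dt - mean(dt)
  null <- vapply(seq_len(n_shuffles),
                 function(k) sum(dtc[sample.int(n)] * zc) / denom,
                 numeric(1))
  res$null <- null
  res$p_permutation <- if (tail == "lower")
    (1 + sum(null <= res$r)) / (1 + n_shuffles)
  else
    (1 + sum(null >= res$r)) / (1 + n_shuffles)
  res$tail <- tail
  res
}

#' Run the full seed-level drift analysis
#'
#' Convenience pipeline: connectivity maps for every session, between-session
#' pattern similarity, outlier exclusion, drift score and (optionally) its
#' permutation test.
#'
#' @param sessions List of [session_image()]s.
#' @param schedule Matching schedule.
#' @param spec A [seed_spec()].
#' @param target_voxel_ids Target set (default: gray matter).
#' @param k_sd Outlier rule multiplier (default 3).
#' @param n_shuffles Permutation count; 0 skips the permutation test.
#' @param seed Optional RNG seed for the permutation.
#' @return List with `pairs` (the pair table) and `result` (a
#'   `"drift_result"`).
#' @export
drift_analysis <- function(sessions, schedule, spec, target_voxel_ids = NULL,
                           k_sd = 3, n_shuffles = 5000L, seed = NULL) {
  Z <- connectivity_stack(sessions, spec, target_voxel_ids)
  pairs <- exclude_outliers(pairwise_similarity(Z, schedule), k_sd)
  result <- if (n_shuffles > 0)
    permutation_test(pairs, n_shuffles, seed = seed)
  else drift_score(pairs)
  list(pairs = pairs, result = result)
}
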