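# Covariate handling and confound-controlled inference: emotion PCA,
# per-pair covariate deltas, multiple regression on pair similarity, and the
# dependent-correlation comparison between seeds.

#' First principal component of the mood questionnaires
#'
#' Standardizes the questionnaire scores (mean 0, SD 1), eigendecomposes
#' their correlation matrix, and returns the first-principal-component score
#' per session as an aggregate emotion metric. The loading sign is fixed so
#' the first questionnaire loads positively. `lambda` is the fraction of
#' each variable's variance captured by PC1 (squared PC1 loading), as a
#' percentage.
#'
#' @param questionnaires Data frame or matrix of questionnaire scores, one
#'   row per session.
#' @return List of class `"emotion_pca"`: `scores` (mean 0), `loadings`,
#'   `lambda` (percent per variable), `eigenvalues`.
#' @export
emotion_pca <- function(questionnaires) {
  X <- as.matrix(questionnaires)
  if (nrow(X) < 2L) stop_config("PCA needs >= 2 sessions")
  if (anyNA(X)) stop_config("questionnaire table contains missing scores")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_config("zero-variance questionnaire: %s",
                paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- scale(X)
  C <- stats::cor(X)
  eg <- eigen(C, symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  if (v1[1] < 0) v1 <- -v1
  loadings <- v1 * sqrt(eg$values[1])   # correlation of each variable w/ PC1
  scores <- as.numeric(Xs %*% v1)
  structure(list(scores = scores - mean(scores),
                 loadings = stats::setNames(loadings, colnames(X)),
                 lambda = stats::setNames(100 * loadings^2, colnames(X)),
                 eigenvalues = eg$values),
            class = "emotion_pca")
}

#' Attach per-pair covariate deltas to a pair table
#'
#' For every covariate column, the absolute difference between the two
#' sessions' values, stored as `delta_<column>`.
#'
#' @param pairs A pair table from [pairwise_similarity()].
#' @param covariates Data frame with a `session_id` column and the covariate
#'   columns.
#' @param columns Covariate column names (default: every numeric column
#'   except `t_days`).
#' @return The pair table with delta columns appended.
#' @export
pair_covariate_deltas <- function(pairs, covariates, columns = NULL) {
  if (is.null(columns)) {
    num <- vapply(covariates, is.numeric, TRUE)
    columns <- setdiff(names(covariates)[num], c("t_days"))
  }
  i <- match(pairs$session_i, covariates$session_id)
  j <- match(pairs$session_j, covariates$session_id)
  if (anyNA(i) || anyNA(j))
    stop_config("covariates missing for sessions: %s",
                paste(unique(c(pairs$session_i[is.na(i)],
                               pairs$session_j[is.na(j)])), collapse = ", "))
  for (cl in columns) {
    if (anyNA(covariates[[cl]]))
      stop_config("covariate '%s' has missing values", cl)
    pairs[[paste0("delta_", cl)]] <- abs(covariates[[cl]][i] -
                                           covariates[[cl]][j])
  }
  pairs
}

#' Confound-controlled regression of pair similarity
#'
#' Ordinary least squares of `z_similarity` on the elapsed time between
#' sessions and the per-pair covariate deltas, over included pairs.
#' Standard errors are classical; p-values are two-tailed t tests with
#' `n - p - 1` degrees of freedom. A significant `delta_t` coefficient after
#' controlling for hormone, motion and emotion changes indicates drift that
#' is not accounted for by those time-varying factors.
#'
#' @param pairs A pair table with delta columns (see
#'   [pair_covariate_deltas()]).
#' @param predictors Predictor column names; default `delta_t` plus every
#'   `delta_*` column present.
#' @return Data frame of class `"drift_regression"`: `term`, `B`, `SE`, `t`,
#'   `p`, with the fit size in `attr(x, "n")`.
#' @export
drift_regression <- function(pairs, predictors = NULL) {
  use <- pairs[pairs$included, , drop = FALSE]
  if (is.null(predictors))
    predictors <- c("delta_t", grep("^delta_(?!t$)", names(pairs),
                                    perl = TRUE, value = TRUE))
  predictors <- unique(predictors)
  missing_cols <- setdiff(predictors, names(use))
  if (length(missing_cols))
    stop_config("predictors absent from pair table: %s",
                paste(missing_cols, collapse = ", "))
  n <- nrow(use)
  if (n < length(predictors) + 2L)
    stop_analysis("need >= %d included pairs, got %d",
                  length(predictors) + 2L, n)

  X <- as.matrix(use[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    piv <- qrX$pivot[(qrX$rank + 1):(ncol(X) + 1L)]
    stop_numeric("collinear predictors: %s",
                 paste(c("(intercept)", predictors)[piv], collapse = ", "))
  }
  fit <- stats::lm(use$z_similarity ~ X)
  sm <- summary(fit)$coefficients
  out <- data.frame(term = c("(intercept)", predictors),
                    B = sm[, 1], SE = sm[, 2], t = sm[, 3], p = sm[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- n
  class(out) <- c("drift_regression", "data.frame")
  out
}

#' Compare two dependent, overlapping correlations
#'
#' Tests the difference between two correlations that share one variable
#' (here: two seeds' drift scores, which share the elapsed-time variable
#' over a common set of session pairs), using the Meng-Rosenthal-Rubin
#' z test for overlapping dependent correlation coefficients.
#'
#' @param r_jk Seed A's drift score (correlation of its similarity with
#'   elapsed time).
#' @param r_jh Seed B's drift score.
#' @param r_kh Correlation between the two seeds' similarity vectors over
#'   the shared pairs.
#' @param n Number of shared pairs (>= 4).
#' @param alternative `"less"` (default; seed A hypothesized more negative),
#'   `"greater"`, or `"two.sided"`.
#' @return List of class `"dependent_cor_test"`: `z`, `p`, inputs.
#' @export
compare_dependent_correlations <- function(r_jk, r_jh, r_kh, n,
                                           alternative = c("less", "greater",
                                                           "two.sided")) {
  alternative <- match.arg(alternative)
  if (n < 4L) stop_domain("need n >= 4, got %d", n)
  for (r in c(r_jk, r_jh, r_kh))
    if (!is.finite(r) || abs(r) >= 1)
      stop_domain("correlations must lie strictly inside (-1, 1)")

  rbar2 <- (r_jk^2 + r_jh^2) / 2
  f <- min((1 - r_kh) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r_jk) - atanh(r_jh)) *
    sqrt((n - 3) / (2 * (1 - r_kh) * h))
  p <- switch(alternative,
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(-abs(z)))
  structure(list(z = z, p = p, r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n,
                 alternative = alternative),
            class = "dependent_cor_test")
}

#' Shared-pair inputs for a seed-vs-seed drift comparison
#'
#' Restricts two seeds' pair tables to the pairs included for both, and
#' computes the three correlations the dependent-correlation test needs.
#'
#' @param pairs_a,pairs_b Pair tables for the two seeds (same session pairs
#'   before exclusion).
#' @param alternative Passed to [compare_dependent_correlations()].
#' @return A `"dependent_cor_test"`.
#' @export
compare_seed_drifts <- function(pairs_a, pairs_b,
                                alternative = "less") {
  key_a <- paste(pairs_a$session_i, pairs_a$session_j)
  key_b <- paste(pairs_b$session_i, pairs_b$session_j)
  shared <- intersect(key_a[pairs_a$included], key_b[pairs_b$included])
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  n <- length(shared)
  if (n < 4L) stop_domain("only %d shared included pairs", n)
  dt <- pairs_a$delta_t[ia]
  za <- pairs_a$z_similarity[ia]
  zb <- pairs_b$z_similarity[ib]
  compare_dependent_correlations(stats::cor(dt, za), stats::cor(dt, zb),
                                 stats::cor(za, zb), n,
                                 alternative = alternative)
}
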