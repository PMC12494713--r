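# Network-restricted drift decomposition, FDR control, and the permutation
# Kruskal-Wallis test across networks.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of a p-value vector (delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, monotone in the raw-p order and capped at 1.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop_domain("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Network-restricted temporal drift
#'
#' Computes one temporal drift score per cortical network by restricting the
#' between-session pattern similarity to the network's target voxels: the
#' seed's per-session whole-brain map is computed once, then correlated
#' across sessions within each network mask. Each network gets its own
#' outlier pass, drift score, permutation p-value, and a BH-adjusted p
#' across the networks.
#'
#' @param sessions List of [session_image()]s.
#' @param schedule Matching schedule.
#' @param spec A [seed_spec()].
#' @param n_shuffles Permutations per network (default 5000; 0 for
#'   parametric p only).
#' @param seed Optional RNG seed.
#' @param k_sd Outlier rule multiplier.
#' @param min_voxels Minimum voxels per network (default 10).
#' @return List of class `"network_drift"`: `table` (network, r,
#'   p_parametric, p_permutation, p_fdr, n_pairs) and `pairs` (the per-pair
#'   similarity matrix and time labels, as consumed by
#'   [kruskal_wallis_perm()]).
#' @export
network_drift <- function(sessions, schedule, spec, n_shuffles = 5000L,
                          seed = NULL, k_sd = 3, min_voxels = 10L) {
  vox <- sessions[[1]]$voxels
  networks <- sort(unique(vox$network[!is.na(vox$network)]))
  if (!length(networks)) stop_config("no network labels in voxel table")
  sizes <- table(vox$network)
  small <- networks[sizes[networks] < min_voxels]
  if (length(small))
    stop_config("networks below %d voxels: %s", min_voxels,
                paste(small, collapse = ", "))

  gm_ids <- vox$voxel_id[vox$label == "gm"]
  Z <- connectivity_stack(sessions, spec, gm_ids)
  net_of <- vox$network[match(gm_ids, vox$voxel_id)]

  maybe_set_seed(seed)
  tabs <- vector("list", length(networks))
  zmat <- NULL
  included <- NULL
  for (k in seq_along(networks)) {
    Zk <- Z[net_of == networks[k], , drop = FALSE]
    pairs <- exclude_outliers(pairwise_similarity(Zk, schedule), k_sd)
    res <- if (n_shuffles > 0) permutation_test(pairs, n_shuffles)
           else drift_score(pairs)
    tabs[[k]] <- data.frame(network = networks[k], r = res$r,
                            p_parametric = res$p_parametric,
                            p_permutation = res$p_permutation %||% NA_real_,
                            n_pairs = res$n_pairs,
                            stringsAsFactors = FALSE)
    if (is.null(zmat)) {
      zmat <- matrix(NA_real_, nrow(pairs), length(networks),
                     dimnames = list(NULL, networks))
      included <- zmat
      delta_t <- pairs$delta_t
    }
    zmat[, k] <- pairs$z_similarity
    included[, k] <- pairs$included
  }
  tab <- do.call(rbind, tabs)
  raw <- if (n_shuffles > 0) tab$p_permutation else tab$p_parametric
  tab$p_fdr <- bh_fdr(raw)
  structure(list(table = tab,
                 pairs = list(delta_t = delta_t, z = zmat,
                              included = included == 1)),
            class = "network_drift")
}

# tie-corrected Kruskal-Wallis H; returns 0 when all values are identical
kw_h <- function(values, groups) {
  if (length(unique(values)) == 1L) return(0)
  unname(stats::kruskal.test(values, factor(groups))$statistic)
}

#' Permutation Kruskal-Wallis test of drift-score variance across networks
#'
#' Tests whether temporal drift scores differ across networks, pooling the
#' per-subject per-network scores as observations (networks are the groups).
#' The null distribution is built by reshuffling each subject's elapsed-time
#' labels (one shuffle per subject per permutation, shared across that
#' subject's networks so the dependence between networks is preserved),
#' recomputing every drift score, and recomputing H.
#'
#' @param subjects Named list, one element per subject, each being the
#'   `pairs` element of a [network_drift()] result (fields `delta_t`, `z`,
#'   `included`).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional RNG seed.
#' @return List of class `"kw_perm"`: `H`, `p`, `scores` (subject x network
#'   drift scores), `null`.
#' @export
kruskal_wallis_perm <- function(subjects, n_perm = 5000L, seed = NULL) {
  if (length(subjects) < 1L) stop_config("need at least one subject")
  networks <- colnames(subjects[[1]]$z)
  if (length(networks) < 2L) stop_config("need >= 2 networks")

  score_one <- function(sub, dt) {
    vapply(seq_along(networks), function(k) {
      use <- sub$included[, k]
      stats::cor(dt[use], sub$z[use, k])
    }, numeric(1))
  }
  scores <- t(vapply(subjects, function(sub) score_one(sub, sub$delta_t),
                     numeric(length(networks))))
  colnames(scores) <- networks
  groups <- rep(networks, each = length(subjects))
  H_obs <- kw_h(as.vector(scores), groups)

  maybe_set_seed(seed)
  null <- vapply(seq_len(n_perm), function(p) {
    perm <- vapply(subjects, function(sub)
      score_one(sub, sample(sub$delta_t)), numeric(length(networks)))
    kw_h(as.vector(t(perm)), groups)
  }, numeric(1))

  p <- (1 + sum(null >= H_obs)) / (1 + n_perm)
  if (H_obs == 0) p <- 1
  structure(list(H = H_obs, p = p, scores = scores, null = null),
            class = "kw_perm")
}
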