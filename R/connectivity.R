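# Per-session seed-based connectivity maps.

#' Specify a connectivity seed
#'
#' @param name Seed name used in outputs.
#' @param mode `"roi-mean"` (average the series of all voxels carrying
#'   `label`) or `"single-voxel"`.
#' @param label ROI label selecting seed voxels (roi-mean mode, or a
#'   single-voxel label that matches exactly one voxel).
#' @param voxel_id Voxel id selecting the seed voxel (single-voxel mode).
#' @return An object of class `"seed_spec"`.
#' @export
seed_spec <- function(name, mode = c("roi-mean", "single-voxel"),
                      label = NULL, voxel_id = NULL) {
  mode <- match.arg(mode)
  if (is.null(label) && is.null(voxel_id))
    stop_config("seed_spec needs a label or a voxel_id selector")
  structure(list(name = name, mode = mode, label = label,
                 voxel_id = voxel_id), class = "seed_spec")
}

seed_rows <- function(image, spec) {
  vox <- image$voxels
  rows <- if (!is.null(spec$voxel_id)) which(vox$voxel_id %in% spec$voxel_id)
          else which(vox$label == spec$label)
  if (!length(rows))
    stop_config("seed '%s' selects no voxels", spec$name)
  if (spec$mode == "single-voxel" && length(rows) != 1L)
    stop_config("single-voxel seed '%s' matches %d voxels", spec$name,
                length(rows))
  rows
}

#' Extract a seed time series
#'
#' The unweighted mean series over the seed's voxels (roi-mean mode) or the
#' single voxel's series.
#'
#' @param image A [session_image()].
#' @param spec A [seed_spec()].
#' @return Numeric vector, one value per timepoint.
#' @export
seed_series <- function(image, spec) {
  rows <- seed_rows(image, spec)
  if (length(rows) == 1L) as.numeric(image$signal[rows, ])
  else colMeans(image$signal[rows, , drop = FALSE])
}

#' Fisher-Z transform of a correlation coefficient
#'
#' `arctanh` with the argument clipped to +/-(1 - 1e-7), so correlations of
#' exactly +/-1 map to a large finite value rather than infinity.
#'
#' @param r Correlations in `[-1, 1]` (values outside by more than 1e-12 are
#'   a domain error).
#' @return Fisher-Z values, same shape as `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop_domain("correlation outside [-1, 1]: max |r| = %g", max(abs(r)))
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Seed-to-voxel connectivity map for one session
#'
#' Pearson correlation between the seed series and every target voxel's
#' series, Fisher-Z transformed. Zero-variance target series get `z = 0`
#' (with a warning) so the target dimension is identical across sessions;
#' a zero-variance seed series is an error.
#'
#' @param image A [session_image()].
#' @param spec A [seed_spec()].
#' @param target_voxel_ids Voxel ids of the target set; defaults to all
#'   gray-matter (`label == "gm"`) voxels.
#' @return Data frame with columns `voxel_id` and `z`, and attributes
#'   `seed` and `session_id`.
#' @export
connectivity_map <- function(image, spec, target_voxel_ids = NULL) {
  if (ncol(image$signal) < 3L)
    stop_analysis("connectivity needs >= 3 timepoints")
  target_voxel_ids <- target_voxel_ids %||%
    image$voxels$voxel_id[image$voxels$label == "gm"]
  trow <- match(target_voxel_ids, image$voxels$voxel_id)
  if (anyNA(trow))
    stop_analysis("%d target voxel ids absent from image", sum(is.na(trow)))

  s <- seed_series(image, spec)
  if (stats::sd(s) == 0)
    stop_analysis("seed '%s' series has zero variance", spec$name)
  Y <- image$signal[trow, , drop = FALSE]
  r <- as.vector(suppressWarnings(stats::cor(s, t(Y))))  # NA handled below
  if (anyNA(r)) {
    warning(sprintf("%d zero-variance target voxels set to z = 0",
                    sum(is.na(r))), call. = FALSE)
    r[is.na(r)] <- 0
  }
  out <- data.frame(voxel_id = target_voxel_ids, z = fisher_z(r))
  attr(out, "seed") <- spec$name
  attr(out, "session_id") <- image$session_id
  out
}

#' Stack per-session connectivity maps into a matrix
#'
#' Convenience wrapper running [connectivity_map()] over a list of sessions
#' with a common target set.
#'
#' @param sessions List of [session_image()]s.
#' @param spec A [seed_spec()].
#' @param target_voxel_ids Common target set (default: gray matter of the
#'   first session).
#' @return Numeric matrix, targets x sessions, of Fisher-Z values; target
#'   voxel ids as rownames.
#' @export
connectivity_stack <- function(sessions, spec, target_voxel_ids = NULL) {
  target_voxel_ids <- target_voxel_ids %||%
    sessions[[1]]$voxels$voxel_id[sessions[[1]]$voxels$label == "gm"]
  Z <- vapply(sessions,
              function(img) connectivity_map(img, spec, target_voxel_ids)$z,
              numeric(length(target_voxel_ids)))
  rownames(Z) <- as.character(target_voxel_ids)
  colnames(Z) <- vapply(sessions, function(img) img$session_id, "")
  Z
}
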