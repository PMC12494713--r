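#' Construct a session image
#'
#' A session image is the in-memory representation of one scanning session:
#' a voxels-by-timepoints signal matrix together with the voxel coordinate
#' table and the repetition time.
#'
#' @param signal Numeric matrix, voxels in rows, timepoints in columns.
#' @param voxels Data frame with one row per signal row; must contain
#'   `voxel_id`, `x_mm`, `y_mm`, `z_mm` and `label`.
#' @param tr_s Repetition time in seconds.
#' @param session_id Optional session identifier.
#' @return An object of class `"session_image"`.
#' @export
session_image <- function(signal, voxels, tr_s, session_id = NA_character_) {
  signal <- as.matrix(signal)
  if (anyNA(signal))
    stop_format("signal matrix contains %d missing values", sum(is.na(signal)))
  need <- c("voxel_id", "x_mm", "y_mm", "z_mm", "label")
  if (!all(need %in% names(voxels)))
    stop_format("voxel table must contain columns: %s",
                paste(need, collapse = ", "))
  if (nrow(voxels) != nrow(signal))
    stop_format("voxel table has %d rows but signal has %d",
                nrow(voxels), nrow(signal))
  if (!is.numeric(tr_s) || tr_s <= 0)
    stop_config("tr_s must be a positive number")
  rownames(signal) <- as.character(voxels$voxel_id)
  structure(list(signal = signal, voxels = voxels, tr_s = tr_s,
                 session_id = session_id),
            class = "session_image")
}

#' @export
print.session_image <- function(x, ...) {
  cat(sprintf("<session_image %s: %d voxels x %d timepoints, TR = %gs>\n",
              x$session_id, nrow(x$signal), ncol(x$signal), x$tr_s))
  invisible(x)
}

#' Number of timepoints in a session image
#' @param image A `session_image`.
#' @return Integer count of timepoints.
#' @export
n_timepoints <- function(image) ncol(image$signal)
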