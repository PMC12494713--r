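#' Phantom voxel layout
#'
#' Builds the coordinate table of the synthetic brain used by the generator
#' and the analysis: a set of seed regions of interest (anterolateral and
#' posteromedial entorhinal cortex, a strip of hippocampal voxels spanning the
#' longitudinal axis, and two control regions, primary motor cortex and
#' perirhinal cortex) plus a field of gray-matter target voxels partitioned
#' into 17 named cortical networks.
#'
#' Coordinates follow the right/anterior/superior-positive (RAS) millimetre
#' convention, so larger `y_mm` is more anterior. Hippocampal voxels are laid
#' out along y and split at the median into anterior (`ahpc`) and posterior
#' (`phpc`) halves; entorhinal voxels carry `alec`/`pmec` subregion labels.
#' The phantom is a coordinate table, not a realistic brain: the analysis
#' operates on voxel-by-time matrices, and rendering to a 3D NIfTI grid is a
#' thin serialization layer (see [write_phantom()]).
#'
#' @param n_per_network Target voxels per network (default 18, giving 306
#'   gray-matter targets over 17 networks).
#' @param hpc_n Number of hippocampal voxels along the longitudinal axis
#'   (default 12; must be >= 10 so the axis spans >= 10 distinct y values).
#' @param roi_n Voxels per entorhinal/control seed ROI (default 4).
#' @param spacing_mm Voxel spacing in millimetres (default 2).
#' @return A data frame with columns `voxel_id`, `x_mm`, `y_mm`, `z_mm`,
#'   `label` (`ec_al`, `ec_pm`, `hpc`, `m1`, `prc`, or `gm`), `network`
#'   (17 network names for `gm` voxels, `NA` otherwise) and `subregion`
#'   (`ahpc`/`phpc`, `alec`/`pmec`, `NA` otherwise).
#' @export
phantom_layout <- function(n_per_network = 18L, hpc_n = 12L, roi_n = 4L,
                           spacing_mm = 2) {
  if (hpc_n < 10L)
    stop_config("hippocampal strip needs >= 10 voxels, got %d", hpc_n)
  if (n_per_network < 1L || roi_n < 1L)
    stop_config("n_per_network and roi_n must be positive")

  networks <- yeo17_names()
  s <- spacing_mm

  roi_block <- function(label, x0, y0, z0, n) {
    # compact cluster of n voxels around (x0, y0, z0)
    g <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:ceiling(n / 4))
    g <- g[seq_len(n), ]
    data.frame(x_mm = x0 + g$dx * s, y_mm = y0 + g$dy * s, z_mm = z0 + g$dz * s,
               label = label, network = NA_character_,
               subregion = NA_character_, stringsAsFactors = FALSE)
  }

  ec_al <- roi_block("ec_al", x0 = -28, y0 = -2, z0 = -34, n = roi_n)
  ec_al$subregion <- "alec"
  ec_pm <- roi_block("ec_pm", x0 = -22, y0 = -14, z0 = -30, n = roi_n)
  ec_pm$subregion <- "pmec"
  m1  <- roi_block("m1",  x0 = -38, y0 = -20, z0 = 54, n = roi_n)
  prc <- roi_block("prc", x0 = -32, y0 = -8,  z0 = -38, n = roi_n)

  # hippocampal strip: one voxel per y step from posterior (-) to anterior (+)
  hpc_y <- seq(-40, by = s, length.out = hpc_n)
  hpc <- data.frame(x_mm = -26, y_mm = hpc_y, z_mm = -16,
                    label = "hpc", network = NA_character_,
                    subregion = ifelse(hpc_y > stats::median(hpc_y), "ahpc", "phpc"),
                    stringsAsFactors = FALSE)

  # gray-matter targets on a grid, partitioned contiguously into networks
  n_gm <- n_per_network * length(networks)
  side <- ceiling(sqrt(n_gm))
  g <- expand.grid(ix = seq_len(side), iy = seq_len(side))
  g <- g[seq_len(n_gm), ]
  gm <- data.frame(x_mm = 10 + g$ix * s, y_mm = -60 + g$iy * s,
                   z_mm = 30, label = "gm",
                   network = rep(networks, each = n_per_network),
                   subregion = NA_character_, stringsAsFactors = FALSE)

  out <- rbind(ec_al, ec_pm, hpc, m1, prc, gm)
  out <- data.frame(voxel_id = seq_len(nrow(out)), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "spacing_mm") <- s
  out
}

#' Names of the 17 cortical networks used by the phantom
#'
#' @return Character vector of length 17.
#' @export
yeo17_names <- function() {
  c("VisualA", "VisualB", "SomMotA", "SomMotB", "DorsAttnA", "DorsAttnB",
    "SalVentAttnA", "SalVentAttnB", "LimbicA", "LimbicB", "ContA", "ContB",
    "ContC", "DefaultA", "DefaultB", "DefaultC", "TempPar")
}
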