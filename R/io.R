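# NIfTI / TSV serialization of phantom datasets and loading of session data.

# map the layout's mm coordinates onto a regular grid; returns 1-based index
# matrix, grid dimensions and the 4x4 RAS affine
layout_grid <- function(layout) {
  s <- attr(layout, "spacing_mm") %||% 2
  origin <- c(min(layout$x_mm), min(layout$y_mm), min(layout$z_mm))
  idx <- cbind((layout$x_mm - origin[1]) / s,
               (layout$y_mm - origin[2]) / s,
               (layout$z_mm - origin[3]) / s)
  if (max(abs(idx - round(idx))) > 1e-6)
    stop_config("layout coordinates are not on a regular %g mm grid", s)
  idx <- round(idx) + 1L
  dim3 <- apply(idx, 2, max)
  affine <- diag(c(s, s, s, 1))
  affine[1:3, 4] <- origin   # world coordinate of the first grid cell
  list(idx = idx, dim = dim3, affine = affine, spacing = s)
}

# region-level integer codes for the labels volume
label_codes <- function(layout) {
  region <- ifelse(layout$label == "gm", layout$network, layout$label)
  regions <- unique(region)
  data.frame(code = seq_along(regions), region = regions,
             stringsAsFactors = FALSE)
}

as_nifti_with_affine <- function(arr, affine, tr_s = NULL) {
  img <- RNifti::asNifti(arr)
  sp <- abs(affine[1, 1])
  RNifti::pixdim(img) <- if (length(dim(arr)) == 4L) c(sp, sp, sp, tr_s %||% 1)
                         else rep(sp, 3)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

#' Write a phantom dataset to disk
#'
#' Serializes a simulated dataset as one 4D NIfTI per session plus an
#' integer-coded labels NIfTI, a label lookup TSV, a session metadata TSV
#' (timestamps, motion, hormone and questionnaire columns) and a JSON ground
#' truth file (per-seed drift rates and covariate couplings).
#'
#' @param sim Result of [simulate_sessions()].
#' @param layout The layout the phantom was generated from.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(sim, layout, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- layout_grid(layout)
  codes <- label_codes(layout)
  region <- ifelse(layout$label == "gm", layout$network, layout$label)

  lab_arr <- array(0L, g$dim)
  lab_arr[g$idx] <- codes$code[match(region, codes$region)]
  labels_path <- file.path(dir, "labels.nii.gz")
  RNifti::writeNifti(as_nifti_with_affine(lab_arr, g$affine), labels_path)

  paths <- labels_path
  for (img in sim$sessions) {
    T <- ncol(img$signal)
    arr <- array(0, c(g$dim, T))
    flat <- g$idx[, 1] + g$dim[1] * (g$idx[, 2] - 1) +
      prod(g$dim[1:2]) * (g$idx[, 3] - 1)
    vol <- prod(g$dim)
    for (t in seq_len(T)) arr[flat + (t - 1) * vol] <- img$signal[, t]
    p <- file.path(dir, sprintf("%s_bold.nii.gz", img$session_id))
    RNifti::writeNifti(as_nifti_with_affine(arr, g$affine, img$tr_s), p,
                       datatype = "float")
    paths <- c(paths, p)
  }

  lt_path <- file.path(dir, "labels.tsv")
  utils::write.table(codes, lt_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  md_path <- file.path(dir, "sessions.tsv")
  utils::write.table(sim$covariates, md_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(units = sim$truth$units,
                            couplings = as.list(sim$truth$couplings)),
                       gt_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, lt_path, md_path, gt_path))
}

#' Load one session from NIfTI files
#'
#' Reads a 4D image and an integer labels volume, checks that their grids
#' agree, and assembles a [session_image()] containing the labeled voxels
#' (label 0 is background and is excluded). Voxel mm coordinates are taken
#' from the image affine (right/anterior/superior-positive). Hippocampal
#' voxels are split into anterior/posterior subregions at their median y.
#'
#' @param image_path Path to the 4D NIfTI.
#' @param labels_path Path to the integer-coded labels NIfTI.
#' @param label_table Data frame mapping `code` to `region` (as written by
#'   [write_phantom()]); when `NULL` labels are the integer codes as strings.
#' @param tr_s Repetition time override; taken from the NIfTI header when
#'   `NULL`.
#' @param session_id Optional identifier stored on the result.
#' @return A `session_image`.
#' @export
load_session <- function(image_path, labels_path, label_table = NULL,
                         tr_s = NULL, session_id = NA_character_) {
  img <- RNifti::readNifti(image_path)
  lab <- RNifti::readNifti(labels_path)
  dimg <- dim(img)
  if (length(dimg) != 4L)
    stop_format("%s is not a 4D image", image_path)
  if (!all(dimg[1:3] == dim(lab)[1:3]))
    stop_format("image grid %s does not match labels grid %s",
                paste(dimg[1:3], collapse = "x"),
                paste(dim(lab)[1:3], collapse = "x"))
  if (max(abs(RNifti::xform(img) - RNifti::xform(lab))) > 1e-4)
    stop_format("image and labels affines disagree")

  lab_arr <- as.array(lab)
  vox <- which(lab_arr > 0, arr.ind = TRUE)
  if (!nrow(vox)) stop_format("labels volume contains no labeled voxels")
  world <- RNifti::voxelToWorld(vox, img)
  codes <- lab_arr[vox]
  region <- if (!is.null(label_table))
    label_table$region[match(codes, label_table$code)]
  else as.character(codes)

  mat <- matrix(as.array(img)[cbind(vox[rep(seq_len(nrow(vox)), dimg[4]), ],
                                    rep(seq_len(dimg[4]), each = nrow(vox)))],
                nrow = nrow(vox))
  if (anyNA(mat))
    stop_format("image contains NaN values in %d labeled voxels",
                sum(rowSums(is.na(mat)) > 0))

  nets <- yeo17_names()
  voxels <- data.frame(
    voxel_id = seq_len(nrow(vox)),
    x_mm = world[, 1], y_mm = world[, 2], z_mm = world[, 3],
    label = ifelse(region %in% nets, "gm", region),
    network = ifelse(region %in% nets, region, NA_character_),
    subregion = NA_character_, stringsAsFactors = FALSE)
  hpc <- voxels$label == "hpc"
  if (any(hpc))
    voxels$subregion[hpc] <-
      ifelse(voxels$y_mm[hpc] > stats::median(voxels$y_mm[hpc]), "ahpc", "phpc")
  voxels$subregion[voxels$label == "ec_al"] <- "alec"
  voxels$subregion[voxels$label == "ec_pm"] <- "pmec"

  if (is.null(tr_s)) {
    tr_s <- RNifti::pixdim(img)[4]
    if (!is.finite(tr_s) || tr_s <= 0)
      stop_format("repetition time missing from header; pass tr_s explicitly")
  }
  session_image(mat, voxels, tr_s, session_id = session_id)
}

#' Read the session metadata TSV written by [write_phantom()]
#' @param path Path to `sessions.tsv`.
#' @return Data frame of per-session metadata.
#' @export
read_session_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
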