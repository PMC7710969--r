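#' @importFrom stats rnorm sd cor cov pt qt var convolve shapiro.test p.adjust
#'   dgamma quantile runif median
#' @importFrom utils head tail write.table read.table
NULL

# ---- affine helpers ---------------------------------------------------------

#' Build a voxel-to-mm affine for a regular grid
#'
#' Returns a 4x4 matrix mapping 0-based voxel indices to mm coordinates, with
#' the grid centre at the mm origin (isotropic or anisotropic voxels).
#'
#' @param voxel_size_mm numeric scalar or length-3 vector of voxel edges (mm).
#' @param grid_shape integer length-3 grid dimensions.
#' @return 4x4 affine matrix.
#' @export
make_affine <- function(voxel_size_mm, grid_shape) {
  vs <- rep_len(as.numeric(voxel_size_mm), 3L)
  stopifnot(all(vs > 0), length(grid_shape) == 3L, all(grid_shape >= 1))
  aff <- diag(c(vs, 1))
  aff[1:3, 4] <- -(grid_shape - 1) / 2 * vs
  aff
}

#' Convert 1-based voxel indices to mm coordinates
#'
#' @param affine 4x4 voxel-to-mm map (0-based voxel convention).
#' @param ijk integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(affine, ijk) {
  ijk <- rbind(ijk)
  storage.mode(ijk) <- "double"
  xyz <- cbind(ijk - 1, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

#' Convert mm coordinates to (fractional) 1-based voxel indices
#' @param affine 4x4 voxel-to-mm map.
#' @param xyz n x 3 matrix or length-3 vector of mm coordinates.
#' @return n x 3 matrix of fractional 1-based voxel indices.
#' @export
mm_to_voxel <- function(affine, xyz) {
  xyz <- rbind(xyz)
  ijk0 <- cbind(xyz, 1) %*% t(solve(affine))
  ijk0[, 1:3, drop = FALSE] + 1
}

# ---- BoldImage --------------------------------------------------------------

#' Construct a 4D BOLD image container
#'
#' @param data 4D numeric array (x, y, z, t) of signal values.
#' @param tr_seconds repetition time in seconds.
#' @param affine 4x4 voxel-to-mm affine.
#' @param run_id character run label.
#' @return object of class `bold_image`.
#' @export
bold_image <- function(data, tr_seconds, affine, run_id = "run-1") {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (dim(data)[4] < 2) stop("a BOLD image needs at least 2 volumes")
  if (!(tr_seconds > 0)) stop("tr_seconds must be positive")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  structure(list(data = data, tr_seconds = tr_seconds, affine = affine,
                 run_id = run_id),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image %s: %dx%dx%d voxels, %d volumes, TR %.3g s>\n",
              x$run_id, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' Number of volumes in a BOLD image
#' @param bold a `bold_image`.
#' @return integer count of time points.
#' @export
n_volumes <- function(bold) dim(bold$data)[4]

#' Flatten a BOLD image to a voxel x time matrix
#' @param bold a `bold_image`.
#' @return numeric matrix with one row per voxel (column-major voxel order).
#' @export
bold_matrix <- function(bold) {
  d <- dim(bold$data)
  matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
}

#' Rebuild a BOLD image from a voxel x time matrix
#' @param mat voxel x time matrix in column-major voxel order.
#' @param template a `bold_image` providing geometry and TR.
#' @return a `bold_image`.
#' @export
matrix_to_bold <- function(mat, template) {
  d <- dim(template$data)
  stopifnot(nrow(mat) == prod(d[1:3]))
  bold_image(array(mat, dim = c(d[1:3], ncol(mat))),
             template$tr_seconds, template$affine, template$run_id)
}

# ---- LabelVolume ------------------------------------------------------------

#' Fixed tissue vocabulary for labelled head volumes
#' @return character vector of recognised tissue names.
#' @export
tissue_vocabulary <- function() {
  c("skin", "bone", "CSF", "GM", "WM", "air", "gel", "electrode",
    "tumor_enhancing", "tumor_nonenhancing", "necrosis", "edema")
}

#' Construct a labelled head volume
#'
#' @param labels 3D integer array; 0 means background (outside the head).
#' @param label_map named integer vector mapping tissue name -> label value.
#' @param voxel_size_mm voxel edge length(s), mm.
#' @param affine optional 4x4 affine; defaults to a centred grid.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, label_map, voxel_size_mm, affine = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (!all(names(label_map) %in% tissue_vocabulary()))
    stop("unknown tissue name(s): ",
         paste(setdiff(names(label_map), tissue_vocabulary()), collapse = ", "))
  used <- setdiff(unique(as.integer(labels)), 0L)
  if (!all(used %in% label_map))
    stop("labels present in the volume but absent from label_map: ",
         paste(setdiff(used, label_map), collapse = ", "))
  if (is.null(affine)) affine <- make_affine(voxel_size_mm, dim(labels))
  structure(list(labels = labels, label_map = label_map,
                 voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
                 affine = affine),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume %dx%dx%d @ %.3g mm: %s>\n", d[1], d[2], d[3],
              x$voxel_size_mm[1],
              paste(names(x$label_map), collapse = ", ")))
  invisible(x)
}

# ---- NIfTI / TSV I/O --------------------------------------------------------

#' Write a BOLD image or label volume as NIfTI-1
#' @param x a `bold_image`, `label_volume`, or 3D array with `affine` attr.
#' @param path output path (.nii or .nii.gz).
#' @param affine affine used when `x` is a bare array.
#' @return the path, invisibly.
#' @export
write_nifti <- function(x, path, affine = NULL) {
  if (inherits(x, "bold_image")) {
    arr <- x$data; aff <- x$affine
  } else if (inherits(x, "label_volume")) {
    arr <- x$labels; aff <- x$affine
  } else {
    arr <- x; aff <- if (is.null(affine)) diag(4) else affine
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path NIfTI file path.
#' @return list with `data` array and `affine` matrix.
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Write a motion trace as 6-column TSV
#' @param motion a `motion_trace`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_motion_tsv <- function(motion, path) {
  df <- as.data.frame(motion$params)
  names(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 6-column motion TSV
#' @param path TSV path with header.
#' @return a `motion_trace`.
#' @export
read_motion_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  motion_trace(as.matrix(df))
}

# ---- misc -------------------------------------------------------------------

#' Derive a reproducible stage seed from a master seed and a label
#'
#' Stable 31-bit polynomial hash of the label mixed with the master seed, so
#' that per-stage random streams are decoupled but fully determined by the
#' master seed.
#' @param master_seed integer master seed.
#' @param label character stage label.
#' @return integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, label) {
  h <- as.numeric(master_seed) %% 2147483647
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% 2147483647
  as.integer(h + 1)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

`%||%` <- function(a, b) if (is.null(a)) b else a
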