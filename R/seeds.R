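# Subject-specific seed definition from task fMRI: optional spatial smoothing,
# block GLM with high-pass basis, peak-voxel selection with an anatomical
# fallback, and 6-mm sphere construction.

#' Resolve the voxel set of a sphere
#'
#' Exactly the voxels whose centres lie within `radius_mm` of `center_mm`,
#' clipped at the grid boundary.
#'
#' @param center_mm length-3 centre (mm).
#' @param radius_mm sphere radius (> 0).
#' @param affine 4x4 voxel-to-mm map.
#' @param grid_shape length-3 grid dimensions.
#' @return list: `ijk` (n x 3, 1-based), `linear` (column-major indices).
#' @export
resolve_sphere <- function(center_mm, radius_mm, affine, grid_shape) {
  stopifnot(radius_mm > 0)
  cv <- mm_to_voxel(affine, center_mm)[1, ]
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  lo <- pmax(1L, floor(cv - radius_mm / vs - 1))
  hi <- pmin(grid_shape, ceiling(cv + radius_mm / vs + 1))
  if (any(lo > hi)) stop("sphere lies entirely outside the grid")
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  xyz <- voxel_to_mm(affine, ijk)
  keep <- rowSums(sweep(xyz, 2, center_mm)^2) <= radius_mm^2 + 1e-12
  if (!any(keep)) stop("sphere lies entirely outside the grid")
  ijk <- ijk[keep, , drop = FALSE]
  linear <- ijk[, 1] + (ijk[, 2] - 1) * grid_shape[1] +
    (ijk[, 3] - 1) * prod(grid_shape[1:2])
  list(ijk = ijk, linear = as.integer(linear))
}

#' Spherical region of interest
#'
#' @param center_mm centre in mm.
#' @param affine,grid_shape grid geometry used to resolve the voxel set.
#' @param radius_mm sphere radius (default 6 mm, the study convention).
#' @param side `"left"` or `"right"`.
#' @return object of class `roi_sphere` with the resolved voxel set.
#' @export
roi_sphere <- function(center_mm, affine, grid_shape, radius_mm = 6,
                       side = c("left", "right")) {
  side <- match.arg(side)
  vs <- resolve_sphere(center_mm, radius_mm, affine, grid_shape)
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 voxel_set = vs, side = side),
            class = "roi_sphere")
}

#' @export
print.roi_sphere <- function(x, ...) {
  cat(sprintf("<roi_sphere %s: centre (%.1f, %.1f, %.1f) mm, r = %g mm, %d voxels>\n",
              x$side, x$center_mm[1], x$center_mm[2], x$center_mm[3],
              x$radius_mm, nrow(x$voxel_set$ijk)))
  invisible(x)
}

#' Serialise a seed as JSON
#' @param roi a [roi_sphere()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_seed_json <- function(roi, path) {
  jsonlite::write_json(list(center_mm = roi$center_mm,
                            radius_mm = roi$radius_mm, side = roi$side),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Separable Gaussian smoothing along one array axis (kernel in mm).
smooth_axis <- function(arr, axis, sigma_mm, step_mm) {
  n <- dim(arr)[axis]
  off <- outer(seq_len(n), seq_len(n), "-") * step_mm
  K <- exp(-off^2 / (2 * sigma_mm^2))
  K[abs(off) > 3 * sigma_mm] <- 0
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(seq_along(dim(arr)), axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- K %*% matrix(a, nrow = n)
  aperm(array(m, d), order(perm))
}

#' Gaussian spatial smoothing of a BOLD image
#'
#' Separable Gaussian filter applied volume-wise, kernel width in mm so
#' anisotropic voxels are handled; edges use renormalised (truncated) kernels.
#'
#' @param bold a [bold_image()].
#' @param fwhm_mm kernel full width at half maximum (mm).
#' @return smoothed [bold_image()].
#' @export
smooth_bold <- function(bold, fwhm_mm = 6) {
  if (fwhm_mm <= 0) return(bold)
  sig <- fwhm_to_sigma(fwhm_mm)
  vs <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
  a <- bold$data
  for (ax in 1:3) a <- smooth_axis(a, ax, sig, vs[ax])
  bold_image(a, bold$tr_seconds, bold$affine, bold$run_id)
}

#' Block-design GLM t-map
#'
#' Per-voxel OLS of the BOLD series on the task regressor (boxcar convolved
#' with the canonical HRF), a discrete-cosine high-pass basis, and an
#' intercept; the returned map is the t statistic for the task effect
#' (task > rest contrast).
#'
#' @param task_bold a [bold_image()].
#' @param design a [block_design()] covering all volumes.
#' @param smooth_fwhm_mm spatial smoothing applied before the fit
#'   (default 6 mm; 0 disables).
#' @param cutoff_hz high-pass cutoff for the nuisance basis.
#' @return object of class `t_map`: 3D `values`, `df`, `contrast`, `affine`.
#' @export
run_block_glm <- function(task_bold, design, smooth_fwhm_mm = 6,
                          cutoff_hz = 0.009) {
  nt <- n_volumes(task_bold)
  if (design$n_volumes != nt) stop("design must cover all volumes")
  if (smooth_fwhm_mm > 0) task_bold <- smooth_bold(task_bold, smooth_fwhm_mm)
  reg <- task_regressor(design)
  hp <- build_highpass_basis(nt, task_bold$tr_seconds, cutoff_hz)
  X <- cbind(task = reg, hp, intercept = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient task design")
  Y <- t(bold_matrix(task_bold))
  beta <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- nt - qrX$rank
  sigma2 <- colSums(res^2) / df
  XtXinv_task <- chol2inv(qr.R(qrX))[1, 1]
  tval <- beta[1, ] / sqrt(sigma2 * XtXinv_task)
  tval[sigma2 == 0] <- 0
  d3 <- dim(task_bold$data)[1:3]
  structure(list(values = array(tval, d3), df = df,
                 contrast = "task > rest", affine = task_bold$affine),
            class = "t_map")
}

#' Pick the peak-activation seed with anatomical fallback
#'
#' Voxels are ranked by t value; the highest-ranked voxel inside
#' `allowed_mask` becomes the sphere centre. Voxels outside the mask are
#' skipped in rank order — if the global peak falls in an implausible
#' location (e.g. cerebellum), the next highest admissible voxel is used.
#' Ties are broken by the lower linear voxel index, so selection is
#' deterministic.
#'
#' @param tmap a `t_map` from [run_block_glm()].
#' @param allowed_mask 3D logical array of admissible centre voxels.
#' @param radius_mm sphere radius (default 6 mm).
#' @param side `"left"` or `"right"`, recorded on the seed.
#' @return a [roi_sphere()].
#' @export
pick_peak_seed <- function(tmap, allowed_mask, radius_mm = 6,
                           side = c("left", "right")) {
  side <- match.arg(side)
  if (!any(allowed_mask)) stop("allowed mask is empty")
  tv <- as.vector(tmap$values)
  ok <- as.vector(allowed_mask) & is.finite(tv)
  if (!any(ok)) stop("no voxel in the mask has a finite t value")
  idx <- which(ok)
  best <- idx[order(-tv[idx], idx)][1]
  d3 <- dim(tmap$values)
  ijk <- arrayInd(best, d3)
  center <- voxel_to_mm(tmap$affine, ijk)[1, ]
  roi_sphere(center, tmap$affine, d3, radius_mm, side)
}
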