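# Resting-state denoising: outlier flagging from global signal and framewise
# displacement, aCompCor nuisance components, discrete-cosine high-pass basis,
# and joint OLS confound regression.

#' Framewise displacement from rigid-body motion parameters
#'
#' Sum of absolute volume-to-volume changes of the six parameters, rotations
#' converted to arc length on a sphere of given radius.
#'
#' @param motion a [motion_trace()].
#' @param rot_radius_mm radius used to convert radians to mm (default 50).
#' @return numeric vector, one value per volume; the first is 0.
#' @export
framewise_displacement <- function(motion, rot_radius_mm = 50) {
  p <- motion$params
  d <- abs(diff(p))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rot_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Flag outlier volumes from global signal and motion
#'
#' A volume is flagged when its global-signal z-score exceeds `z_thresh` in
#' absolute value or its framewise displacement exceeds `fd_thresh`.
#'
#' @param bold a [bold_image()].
#' @param motion a [motion_trace()] with one row per volume.
#' @param z_thresh global-signal z threshold (default 5).
#' @param fd_thresh framewise-displacement threshold in mm (default 0.9).
#' @return object of class `outlier_mask`: logical flags plus the thresholds
#'   and the per-volume diagnostics.
#' @export
detect_outliers <- function(bold, motion, z_thresh = 5, fd_thresh = 0.9) {
  stopifnot(z_thresh > 0, fd_thresh > 0)
  nt <- n_volumes(bold)
  if (nt < 3) stop("outlier detection needs at least 3 volumes")
  if (motion$n != nt) stop("motion trace length must equal number of volumes")
  gs <- colMeans(bold_matrix(bold))
  s <- sd(gs)
  z <- if (s > 0) (gs - mean(gs)) / s else rep(0, nt)
  fd <- framewise_displacement(motion)
  flags <- abs(z) > z_thresh | fd > fd_thresh
  structure(list(flags = flags, global_z = z, fd = fd,
                 z_thresh = z_thresh, fd_thresh = fd_thresh),
            class = "outlier_mask")
}

#' aCompCor nuisance components
#'
#' First k principal-component time courses of the demeaned noise-mask
#' voxel-by-time matrix, ordered by explained variance — the component-based
#' noise-correction approach using anatomically defined noise voxels
#' (white matter / CSF in real data).
#'
#' @param bold a [bold_image()].
#' @param noise_mask 3D logical array (same grid) or linear voxel indices.
#' @param k number of components (>= 0).
#' @return time x k matrix of unit-norm component time courses, with
#'   attribute `variance` (singular values squared). k = 0 gives 0 columns.
#' @export
compute_acompcor <- function(bold, noise_mask, k) {
  stopifnot(k >= 0)
  idx <- if (is.logical(noise_mask)) which(noise_mask) else as.integer(noise_mask)
  if (!length(idx)) stop("noise mask is empty")
  nt <- n_volumes(bold)
  if (k == 0) return(matrix(numeric(0), nt, 0))
  X <- t(bold_matrix(bold)[idx, , drop = FALSE])   # time x voxels
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = min(k, min(dim(X))), nv = 0)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(pos)
  if (k > r) {
    warning("requested ", k, " aCompCor components but matrix rank is ", r,
            "; returning ", r)
    k <- r
  }
  comps <- sv$u[, seq_len(k), drop = FALSE]
  attr(comps, "variance") <- sv$d[seq_len(k)]^2
  colnames(comps) <- paste0("compcor_", seq_len(ncol(comps)))
  comps
}

#' Discrete-cosine high-pass basis
#'
#' Regression implementation of a high-pass filter: DCT columns spanning all
#' frequencies strictly below the cutoff. The column count is
#' `floor(2 * n_volumes * tr * cutoff_hz)`.
#'
#' @param n_volumes number of volumes.
#' @param tr repetition time, seconds.
#' @param cutoff_hz high-pass cutoff (default 0.009 Hz).
#' @return time x k matrix of cosine regressors (possibly 0 columns).
#' @export
build_highpass_basis <- function(n_volumes, tr, cutoff_hz = 0.009) {
  stopifnot(cutoff_hz > 0)
  if (cutoff_hz >= 1 / (2 * tr)) stop("cutoff is at or above Nyquist")
  K <- floor(2 * n_volumes * tr * cutoff_hz)
  t <- seq_len(n_volumes)
  B <- vapply(seq_len(K),
              function(kk) cos(pi * kk * (2 * t - 1) / (2 * n_volumes)),
              numeric(n_volumes))
  B <- matrix(B, nrow = n_volumes)
  if (K > 0) colnames(B) <- paste0("dct_", seq_len(K))
  B
}

#' Assemble a confound regressor set
#'
#' Motion (6), motion first temporal derivatives (6, backward difference with
#' a leading zero), aCompCor components, one indicator column per flagged
#' outlier volume, and the high-pass cosine basis.
#'
#' @param motion a [motion_trace()] or NULL.
#' @param compcor time x k component matrix or NULL.
#' @param outliers an `outlier_mask` or NULL.
#' @param highpass time x k DCT matrix or NULL.
#' @param n_volumes required when all parts are NULL.
#' @return object of class `confound_set`: a labelled time x p matrix.
#' @export
confound_set <- function(motion = NULL, compcor = NULL, outliers = NULL,
                         highpass = NULL, n_volumes = NULL) {
  parts <- list()
  if (!is.null(motion)) {
    mp <- motion$params
    colnames(mp) <- paste0("motion_", 1:6)
    dmp <- rbind(0, diff(mp))
    colnames(dmp) <- paste0("motion_deriv_", 1:6)
    parts <- c(parts, list(mp, dmp))
    n_volumes <- nrow(mp)
  }
  if (!is.null(compcor) && ncol(compcor)) parts <- c(parts, list(compcor))
  if (!is.null(outliers)) {
    w <- which(outliers$flags)
    if (length(w)) {
      ind <- matrix(0, length(outliers$flags), length(w))
      ind[cbind(w, seq_along(w))] <- 1
      colnames(ind) <- paste0("outlier_", w)
      parts <- c(parts, list(ind))
    }
    n_volumes <- n_volumes %||% length(outliers$flags)
  }
  if (!is.null(highpass) && ncol(highpass)) parts <- c(parts, list(highpass))
  if (is.null(n_volumes)) stop("n_volumes required when no parts given")
  X <- if (length(parts)) do.call(cbind, parts)
       else matrix(numeric(0), n_volumes, 0)
  if (any(vapply(parts, nrow, integer(1)) != n_volumes))
    stop("confound parts disagree on the number of volumes")
  structure(list(matrix = X, n = n_volumes), class = "confound_set")
}

#' Write confounds as TSV with header
#' @param confounds a `confound_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_confounds_tsv <- function(confounds, path) {
  write.table(as.data.frame(confounds$matrix), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Regress confounds out of a BOLD image
#'
#' Per-voxel ordinary least squares against the confound columns plus an
#' always-included intercept; returns the residual series. Collinear columns
#' are dropped with a warning (QR with pivoting).
#'
#' @param bold a [bold_image()].
#' @param confounds a `confound_set` (rows must match volumes).
#' @return residual [bold_image()].
#' @export
regress_confounds <- function(bold, confounds) {
  nt <- n_volumes(bold)
  if (confounds$n != nt) stop("confound rows must match number of volumes")
  X <- cbind(intercept = 1, confounds$matrix)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping ", ncol(X) - qrX$rank, " collinear confound column(s): ",
            paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)],
                  collapse = ", "))
    qrX <- qr(X[, keep, drop = FALSE])
  }
  Y <- t(bold_matrix(bold))                 # time x voxels
  res <- qr.resid(qrX, Y)
  matrix_to_bold(t(res), bold)
}

#' One-run denoising recipe
#'
#' Outlier flagging, confound assembly (motion + derivatives + aCompCor +
#' outlier indicators + DCT high-pass), joint OLS confound regression, and
#' optional per-voxel standardisation of the residuals.
#'
#' @param bold a [bold_image()].
#' @param motion a [motion_trace()].
#' @param noise_mask noise-voxel mask for aCompCor (logical array or indices).
#' @param n_compcor number of aCompCor components (default 5).
#' @param z_thresh,fd_thresh outlier thresholds (see [detect_outliers()]).
#' @param cutoff_hz high-pass cutoff (default 0.009 Hz).
#' @param standardize z-score each voxel's residual series (default TRUE).
#' @return list: `bold` (residual image), `confounds`, `outliers`.
#' @export
preprocess_run <- function(bold, motion, noise_mask, n_compcor = 5,
                           z_thresh = 5, fd_thresh = 0.9, cutoff_hz = 0.009,
                           standardize = TRUE) {
  out <- detect_outliers(bold, motion, z_thresh, fd_thresh)
  cc <- compute_acompcor(bold, noise_mask, n_compcor)
  hp <- build_highpass_basis(n_volumes(bold), bold$tr_seconds, cutoff_hz)
  conf <- confound_set(motion = motion, compcor = cc, outliers = out,
                       highpass = hp)
  res <- regress_confounds(bold, conf)
  if (standardize) {
    m <- bold_matrix(res)
    s <- apply(m, 1, sd)
    s[s == 0] <- 1
    res <- matrix_to_bold(m / s, res)
  }
  list(bold = res, confounds = conf, outliers = out)
}

#' Concatenate runs along time
#' @param runs list of [bold_image()]s sharing grid and TR.
#' @return a [bold_image()] with the combined time axis.
#' @export
concat_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  mats <- lapply(runs, bold_matrix)
  matrix_to_bold(do.call(cbind, mats), runs[[1]])
}
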