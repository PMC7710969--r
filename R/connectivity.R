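# First-level connectivity metrics: interhemispheric Fisher-z, voxel-wise
# intrinsic connectivity (RMS correlation through a truncated SVD), integrated
# local correlation with a Gaussian mm-space kernel, seed-to-voxel maps, and
# ROI averaging.

#' Fisher z transform of a correlation
#' @param r correlation value(s), strictly inside (-1, 1).
#' @return atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("invalid correlation: |r| >= 1")
  atanh(r)
}

# Row-standardise a voxel x time matrix to unit L2 rows so that tcrossprod
# gives Pearson correlations. Zero-variance rows come back as all-zero.
unit_rows <- function(M) {
  M <- M - rowMeans(M)
  nrm <- sqrt(rowSums(M^2))
  nz <- nrm > 0
  M[nz, ] <- M[nz, , drop = FALSE] / nrm[nz]
  list(Z = M, nonzero = nz)
}

#' Connectivity map container
#' @param values numeric vector (length = prod(grid)) or 3D array.
#' @param mask 3D logical analysis mask.
#' @param metric label, e.g. "IC", "LCOR", "fisher_z".
#' @param affine 4x4 voxel-to-mm map.
#' @param normalized logical flag.
#' @return object of class `conn_map`; values outside the mask are NA.
#' @export
conn_map <- function(values, mask, metric, affine, normalized = FALSE) {
  d <- dim(mask)
  v <- array(as.numeric(values), d)
  v[!mask] <- NA_real_
  if (any(!is.finite(v[mask]))) stop("non-finite map values inside the mask")
  structure(list(values = v, mask = mask, metric = metric, affine = affine,
                 normalized = normalized),
            class = "conn_map")
}

#' Default analysis mask: voxels with temporal variance
#' @param bold a [bold_image()].
#' @return 3D logical array.
#' @export
brain_mask <- function(bold) {
  m <- bold_matrix(bold)
  v <- rowSums((m - rowMeans(m))^2) > 0
  array(v, dim(bold$data)[1:3])
}

#' Mean time course of an ROI
#' @param bold a [bold_image()].
#' @param roi a [roi_sphere()].
#' @return numeric series of length n_volumes.
#' @export
roi_series <- function(bold, roi) {
  colMeans(bold_matrix(bold)[roi$voxel_set$linear, , drop = FALSE])
}

#' Interhemispheric connectivity between two seeds
#'
#' Pearson correlation between the ROI-mean residual BOLD time courses of the
#' left and right seeds, Fisher transformed.
#'
#' @param bold residual [bold_image()].
#' @param left,right [roi_sphere()] seeds.
#' @return Fisher z value.
#' @export
interhemispheric_fc <- function(bold, left, right) {
  a <- roi_series(bold, left)
  b <- roi_series(bold, right)
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance ROI series")
  fisher_z(cor(a, b))
}

#' Voxel-wise intrinsic connectivity (RMS correlation)
#'
#' IC(x) = sqrt(mean over in-mask voxels y of r(x, y)^2), the root mean
#' square of a voxel's correlations with every voxel in the analysis mask
#' (self term included). Computed through a rank-K truncated SVD of the
#' standardised voxel x time matrix: with K at least the matrix rank this is
#' exact; smaller K reproduces the dimensionality-reduced variant.
#'
#' @param bold residual [bold_image()].
#' @param mask 3D logical analysis mask (zero-variance voxels are dropped
#'   with a warning).
#' @param n_components SVD truncation order K (default 64).
#' @param normalize z-score the map across in-mask voxels (default TRUE).
#' @return a [conn_map()] (attribute `raw` keeps the unnormalised values
#'   when `normalize` is TRUE).
#' @export
intrinsic_connectivity <- function(bold, mask, n_components = 64,
                                   normalize = TRUE) {
  stopifnot(n_components >= 1)
  idx <- which(mask)
  if (length(idx) < 2) stop("analysis mask needs at least 2 voxels")
  u <- unit_rows(bold_matrix(bold)[idx, , drop = FALSE])
  if (!all(u$nonzero)) {
    warning("dropping ", sum(!u$nonzero), " zero-variance voxel(s) from the mask")
    idx <- idx[u$nonzero]
    if (length(idx) < 2) stop("analysis mask needs at least 2 voxels")
    Z <- u$Z[u$nonzero, , drop = FALSE]
    mask <- array(FALSE, dim(mask)); mask[idx] <- TRUE
  } else Z <- u$Z
  N <- nrow(Z)
  G <- crossprod(Z)                              # time x time Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(eg$values) * length(eg$values) * .Machine$double.eps
  K <- min(n_components, sum(eg$values > tol))
  lam <- eg$values[seq_len(K)]
  P <- Z %*% eg$vectors[, seq_len(K), drop = FALSE]
  ic <- sqrt(rowSums(sweep(P^2, 2, lam, `*`)) / N)
  vals <- rep(NA_real_, length(mask))
  vals[idx] <- ic
  out <- conn_map(vals, mask, "IC", bold$affine, normalized = FALSE)
  if (normalize) {
    raw <- out
    z <- (ic - mean(ic)) / sd(ic)
    vals[idx] <- z
    out <- conn_map(vals, mask, "IC", bold$affine, normalized = TRUE)
    attr(out, "raw") <- raw
  }
  out
}

#' Gaussian kernel specification for local correlation
#' @param fwhm_mm kernel full width at half maximum (default 8 mm).
#' @param truncate_sigmas radius, in sigmas, beyond which weights are zero.
#' @return object of class `kernel_spec` with derived `sigma_mm`.
#' @export
kernel_spec <- function(fwhm_mm = 8, truncate_sigmas = 3) {
  stopifnot(fwhm_mm > 0, truncate_sigmas > 0)
  structure(list(fwhm_mm = fwhm_mm, sigma_mm = fwhm_to_sigma(fwhm_mm),
                 truncate_sigmas = truncate_sigmas),
            class = "kernel_spec")
}

#' Integrated local correlation (LCOR)
#'
#' LCOR(x) is the Gaussian-weighted average of the correlations between voxel
#' x and its spatial neighbours: sum_y w(x - y) r(x, y) / sum_y w(x - y),
#' with w a Gaussian of the given FWHM evaluated on voxel offsets in mm (so
#' anisotropic voxels are weighted correctly) and truncated at 3 sigma. The
#' self term (zero offset, weight 1, r = 1) is included.
#'
#' @param bold residual [bold_image()].
#' @param mask 3D logical analysis mask.
#' @param kernel a [kernel_spec()] (default FWHM 8 mm).
#' @return a [conn_map()].
#' @export
local_correlation <- function(bold, mask, kernel = kernel_spec()) {
  d <- dim(bold$data)
  d3 <- d[1:3]; nt <- d[4]
  vs <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
  sig <- kernel$sigma_mm
  rad <- kernel$truncate_sigmas * sig
  nv <- pmax(0L, floor(rad / vs))
  if (all(nv == 0) && rad < min(vs))
    warning("kernel truncation radius is below one voxel; only the self term remains")
  off <- as.matrix(expand.grid(di = -nv[1]:nv[1], dj = -nv[2]:nv[2],
                               dk = -nv[3]:nv[3]))
  dmm2 <- (off %*% diag(vs, 3))^2
  dist2 <- rowSums(dmm2)
  keep <- dist2 <= rad^2 + 1e-12
  off <- off[keep, , drop = FALSE]
  w <- exp(-dist2[keep] / (2 * sig^2))
  u <- unit_rows(bold_matrix(bold))
  A <- array(u$Z, d)                      # standardised 4D array
  mok <- mask & array(u$nonzero, d3)
  num <- array(0, d3); den <- array(0, d3)
  for (o in seq_len(nrow(off))) {
    s <- off[o, ]
    xr <- list(); yr <- list(); empty <- FALSE
    for (ax in 1:3) {
      x1 <- max(1, 1 - s[ax]); x2 <- min(d3[ax], d3[ax] - s[ax])
      if (x1 > x2) { empty <- TRUE; break }
      xr[[ax]] <- x1:x2
      yr[[ax]] <- (x1 + s[ax]):(x2 + s[ax])
    }
    if (empty) next
    A1 <- A[xr[[1]], xr[[2]], xr[[3]], , drop = FALSE]
    A2 <- A[yr[[1]], yr[[2]], yr[[3]], , drop = FALSE]
    nsub <- prod(dim(A1)[1:3])
    r <- rowSums(matrix(A1 * A2, nsub, nt))
    m1 <- mok[xr[[1]], xr[[2]], xr[[3]], drop = FALSE]
    m2 <- mok[yr[[1]], yr[[2]], yr[[3]], drop = FALSE]
    valid <- as.vector(m1 & m2)
    num[xr[[1]], xr[[2]], xr[[3]]] <-
      num[xr[[1]], xr[[2]], xr[[3]]] + w[o] * r * valid
    den[xr[[1]], xr[[2]], xr[[3]]] <-
      den[xr[[1]], xr[[2]], xr[[3]]] + w[o] * valid
  }
  if (any(den[mok] == 0)) stop("empty neighbourhood for some mask voxel")
  vals <- rep(NA_real_, prod(d3))
  vals[which(mok)] <- (num / pmax(den, .Machine$double.xmin))[which(mok)]
  conn_map(vals, mok, "LCOR", bold$affine)
}

#' Seed-to-voxel Fisher-z map
#'
#' Fisher-transformed Pearson correlation between the seed-mean series and
#' every in-mask voxel. Correlations with |r| = 1 (e.g. the seed's own voxel
#' for a single-voxel seed) are clamped just inside (-1, 1) before the
#' transform; the number of clamped voxels is recorded as attribute
#' `n_clamped`.
#'
#' @param bold residual [bold_image()].
#' @param seed a [roi_sphere()].
#' @param mask 3D logical analysis mask.
#' @return a [conn_map()] of Fisher z values.
#' @export
seed_to_voxel <- function(bold, seed, mask) {
  s <- roi_series(bold, seed)
  if (sd(s) == 0) stop("zero-variance seed series")
  sz <- (s - mean(s)) / sqrt(sum((s - mean(s))^2))
  u <- unit_rows(bold_matrix(bold))
  r <- as.vector(u$Z %*% sz)
  mok <- mask & array(u$nonzero, dim(mask))
  eps <- 1e-7
  clamped <- sum(abs(r[which(mok)]) >= 1 - eps)
  r <- pmin(pmax(r, -1 + eps), 1 - eps)
  out <- conn_map(atanh(r), mok, "fisher_z", bold$affine)
  attr(out, "n_clamped") <- clamped
  out
}

#' Mean map value over an ROI
#' @param map a [conn_map()].
#' @param roi a [roi_sphere()].
#' @return arithmetic mean over the ROI voxels inside the map's mask.
#' @export
roi_mean <- function(map, roi) {
  idx <- roi$voxel_set$linear
  idx <- idx[map$mask[idx]]
  if (!length(idx)) stop("ROI does not intersect the analysis mask")
  mean(map$values[idx])
}
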