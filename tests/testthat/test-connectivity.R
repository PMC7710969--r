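# Connectivity metrics: Fisher z, interhemispheric FC, intrinsic connectivity,
# local correlation, seed-to-voxel maps.

make_roi <- function(center, aff, grid) roi_sphere(center, aff, grid, 6)

test_that("fisher_z matches atanh and rejects degenerate input", {
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-7)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_equal(fisher_z(0), 0)
  expect_error(fisher_z(1), "invalid correlation")
  expect_error(fisher_z(-1.2), "invalid correlation")
})

test_that("interhemispheric FC recovers planted values and edge cases", {
  grid <- c(8, 4, 4)
  aff <- make_affine(4, grid)
  nt <- 400
  L <- make_roi(c(-10, 0, 0), aff, grid)
  R <- make_roi(c(10, 0, 0), aff, grid)
  # identical series in both ROIs: perfect correlation is rejected upstream
  m <- matrix(rnorm(nt), prod(grid), nt, byrow = TRUE)
  expect_error(fisher_z(cor(roi_series(bold_from_matrix(m, grid), L),
                            roi_series(bold_from_matrix(m, grid), R))),
               "invalid correlation")
  # constant ROI errors
  m2 <- matrix(rnorm(prod(grid) * nt), prod(grid), nt)
  m2[L$voxel_set$linear, ] <- 3
  expect_error(interhemispheric_fc(bold_from_matrix(m2, grid), L, R),
               "zero-variance")
  # orthogonal deterministic series: exactly zero
  t1 <- sin(2 * pi * seq_len(nt) / nt)
  t2 <- cos(2 * pi * seq_len(nt) / nt)
  m3 <- matrix(0, prod(grid), nt)
  m3[L$voxel_set$linear, ] <- rep(t1, each = length(L$voxel_set$linear))
  m3[R$voxel_set$linear, ] <- rep(t2, each = length(R$voxel_set$linear))
  expect_lt(abs(interhemispheric_fc(bold_from_matrix(m3, grid), L, R)), 1e-12)
  # planted correlation via the generator, within 3 SE of atanh(0.6)
  tr <- ground_truth(pairwise_r = 0.6, delta_r = 0, seed = 33)
  rb <- make_rest_bold(tr, small_grid, n_volumes = 300)
  Ls <- roi_sphere(tr$region_centers[1, ], rb$pre$affine, small_grid, 6)
  Rs <- roi_sphere(tr$region_centers[2, ], rb$pre$affine, small_grid, 6)
  z <- interhemispheric_fc(rb$pre, Ls, Rs)
  expect_lt(abs(z - atanh(0.6)), 3 / sqrt(300 - 3))
})

test_that("intrinsic connectivity matches the brute-force definition", {
  grid <- c(6, 6, 4)
  nt <- 40
  set.seed(12)
  bold <- random_bold(grid, nt, seed = 12)
  mask <- array(TRUE, grid)
  mask[sample(prod(grid), 20)] <- FALSE   # irregular mask
  ic <- intrinsic_connectivity(bold, mask, n_components = nt, normalize = FALSE)
  idx <- which(mask)
  Rfull <- cor(t(bold_matrix(bold)[idx, ]))
  want <- sqrt(rowMeans(Rfull^2))
  expect_lt(max(abs(ic$values[idx] - want)), 1e-10)
  expect_true(all(is.na(ic$values[!mask])))
})

test_that("intrinsic connectivity analytic cases and invariances", {
  grid <- c(4, 3, 2)
  nt <- 30
  set.seed(13)
  base <- rnorm(nt)
  # all voxels share one series (plus per-voxel scaling): every r = 1, IC = 1
  m <- outer(runif(prod(grid), 0.5, 2), base)
  mask <- array(TRUE, grid)
  ic1 <- intrinsic_connectivity(bold_from_matrix(m, grid), mask,
                                normalize = FALSE)
  expect_equal(unname(ic1$values[mask]), rep(1, prod(grid)), tolerance = 1e-10)
  # two voxels, r = -1: r^2 = 1 for both pairs, IC = 1
  g2 <- c(2, 1, 1)
  m2 <- rbind(base, -base)
  ic2 <- intrinsic_connectivity(bold_from_matrix(m2, g2), array(TRUE, g2),
                                normalize = FALSE)
  expect_equal(unname(ic2$values), array(1, g2), tolerance = 1e-10)
  # invariance to per-voxel affine rescaling
  b <- random_bold(grid, nt, seed = 14)
  sc <- matrix_to_bold(bold_matrix(b) * runif(prod(grid), 0.1, 5) + 7, b)
  v1 <- intrinsic_connectivity(b, mask, normalize = FALSE)$values
  v2 <- intrinsic_connectivity(sc, mask, normalize = FALSE)$values
  expect_equal(v1, v2, tolerance = 1e-9)
  # invariance to a common permutation of time points
  p <- sample(nt)
  bp <- matrix_to_bold(bold_matrix(b)[, p], b)
  v3 <- intrinsic_connectivity(bp, mask, normalize = FALSE)$values
  expect_equal(v1, v3, tolerance = 1e-9)
  # normalised map is a z-score of the raw map
  icn <- intrinsic_connectivity(b, mask, normalize = TRUE)
  raw <- attr(icn, "raw")$values[mask]
  expect_equal(unname(icn$values[mask]),
               unname((raw - mean(raw)) / sd(raw)), tolerance = 1e-12)
  # zero-variance voxels are dropped with a warning
  mz <- bold_matrix(b); mz[3, ] <- 2
  expect_warning(intrinsic_connectivity(matrix_to_bold(mz, b), mask),
                 "zero-variance")
})

test_that("median IC of pure noise shrinks with the series length", {
  # for independent noise E[r^2] ~ 1/T, so IC ~ 1/sqrt(T)
  grid <- c(6, 6, 3)
  mask <- array(TRUE, grid)
  Ts <- c(50, 200, 800)
  med <- vapply(Ts, function(nt) {
    b <- random_bold(grid, nt, seed = nt)
    median(intrinsic_connectivity(b, mask, normalize = FALSE)$values[mask])
  }, numeric(1))
  expect_true(all(diff(med) < 0))
  # analytic level: IC^2 = (1 + (N-1) E[r^2]) / N with E[r^2] = 1/(T-1)
  N <- prod(grid)
  want <- sqrt((1 + (N - 1) / (Ts - 1)) / N)
  expect_lt(max(abs(med - want) / want), 0.15)
})

test_that("local correlation matches closed-form two-voxel value", {
  # two voxels at distance d with correlation r:
  # LCOR = (1 + w r) / (1 + w), w = exp(-d^2 / (2 sigma^2))
  g2 <- c(2, 1, 1)
  nt <- 50
  set.seed(15)
  x <- rnorm(nt); y <- rnorm(nt)
  y <- y - mean(y); x <- x - mean(x)
  y <- y - sum(x * y) / sum(x * x) * x     # orthogonalise
  r <- 0.4
  y2 <- r * x / sd(x) + sqrt(1 - r^2) * y / sd(y)
  m <- rbind(x, y2)
  bold <- bold_from_matrix(m, g2)          # helper uses 4-mm voxels
  k <- kernel_spec(fwhm_mm = 8)
  w <- exp(-16 / (2 * k$sigma_mm^2))
  robs <- cor(x, y2)
  want <- (1 + w * robs) / (1 + w)
  lc <- local_correlation(bold, array(TRUE, g2), k)
  expect_equal(unname(lc$values[1, 1, 1]), want, tolerance = 1e-12)
  expect_equal(unname(lc$values[2, 1, 1]), want, tolerance = 1e-12)
  # identical series everywhere: LCOR = 1
  ident <- bold_from_matrix(outer(rep(1, 8), rnorm(nt)) +
                              outer(runif(8), rep(0, nt)), c(2, 2, 2))
  lid <- local_correlation(ident, array(TRUE, c(2, 2, 2)), k)
  expect_equal(unname(lid$values), array(1, c(2, 2, 2)), tolerance = 1e-10)
  # bounded above by 1 on arbitrary data
  b <- random_bold(c(5, 5, 4), 40, seed = 16)
  lv <- local_correlation(b, array(TRUE, c(5, 5, 4)), k)$values
  expect_true(all(lv <= 1 + 1e-12))
})

test_that("local correlation kernel truncates at the requested radius", {
  # beyond 3 sigma the neighbour contributes nothing: a voxel pair farther
  # apart than the truncation radius gives LCOR exactly 1 (self term only)
  g2 <- c(2, 1, 1)
  nt <- 40
  set.seed(17)
  m <- rbind(rnorm(nt), rnorm(nt))
  k <- kernel_spec(fwhm_mm = 2, truncate_sigmas = 3)  # radius 2.55 mm < 4 mm
  expect_warning(lc <- local_correlation(bold_from_matrix(m, g2),
                                         array(TRUE, g2), k),
                 "self term")
  expect_equal(unname(lc$values), array(1, g2), tolerance = 1e-12)
})

test_that("seed-to-voxel maps match a naive correlation loop", {
  grid <- c(5, 4, 3)
  nt <- 60
  aff <- make_affine(4, grid)
  b <- random_bold(grid, nt, seed = 18)
  vox_center <- voxel_to_mm(aff, c(3, 2, 2))[1, ]
  seed <- roi_sphere(vox_center, aff, grid, 5)
  mask <- array(TRUE, grid)
  cm <- seed_to_voxel(b, seed, mask)
  s <- roi_series(b, seed)
  want <- atanh(vapply(seq_len(prod(grid)), function(i)
    cor(bold_matrix(b)[i, ], s), numeric(1)))
  expect_equal(as.vector(cm$values), want, tolerance = 1e-10)
  expect_identical(attr(cm, "n_clamped"), 0L)
  # a voxel identical to the (single-voxel) seed is clamped, not infinite
  seed1 <- roi_sphere(vox_center, aff, grid, 1)
  cm1 <- seed_to_voxel(b, seed1, mask)
  expect_true(all(is.finite(cm1$values[mask])))
  expect_gte(attr(cm1, "n_clamped"), 1L)
  expect_equal(max(cm1$values, na.rm = TRUE), atanh(1 - 1e-7))
})

test_that("roi_mean averages map values over in-mask ROI voxels", {
  grid <- c(5, 5, 4)
  aff <- make_affine(4, grid)
  mask <- array(TRUE, grid)
  vals <- array(seq_len(prod(grid)), grid)
  cm <- conn_map(vals, mask, "test", aff)
  roi <- roi_sphere(c(0, 0, 0), aff, grid, 6)
  expect_equal(roi_mean(cm, roi), mean(vals[roi$voxel_set$linear]))
  # voxels outside the mask are excluded from the average
  mask2 <- mask; mask2[roi$voxel_set$linear[1]] <- FALSE
  cm2 <- conn_map(vals, mask2, "test", aff)
  expect_equal(roi_mean(cm2, roi),
               mean(vals[roi$voxel_set$linear[-1]]))
  expect_error(roi_mean(conn_map(vals, array(FALSE, grid), "t", aff), roi),
               "does not intersect")
})
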