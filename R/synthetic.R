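# Synthetic study inputs: paired resting runs with planted inter-regional
# correlation, block-design task runs, motion traces, and multi-compartment
# spherical head phantoms. Every generator is a pure function of
# (parameters, seed).

#' Ground-truth record for a synthetic subject
#'
#' Holds everything needed to generate and later score a subject's data:
#' region centres, the planted inter-regional correlation matrix per session,
#' the pre-to-post change, task activation locus/amplitude, and noise level.
#'
#' @param region_centers n x 3 matrix of region centres (mm). Default: left
#'   and right motor-cortex stand-ins at x = -/+28 mm.
#' @param pairwise_r symmetric matrix of planted pre-session correlations
#'   between region-mean time courses, or a scalar applied to all pairs.
#' @param delta_r pre-to-post additive change, matrix or scalar (scalar is
#'   applied to the (1,2) pair only). Post correlations must stay in (-1, 1).
#' @param region_radius_mm radius of each signal region (mm).
#' @param signal_amplitude standard deviation of the shared regional signal,
#'   in raw signal units (baseline is 100).
#' @param noise_sd iid voxel noise standard deviation.
#' @param activation_center mm coordinate of the task activation locus.
#' @param activation_amplitude task response amplitude as percent of the
#'   100-unit baseline.
#' @param seed integer seed governing all randomness for this subject.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(region_centers = rbind(left_M1 = c(-28, -16, 24),
                                                right_M1 = c(28, -16, 24)),
                         pairwise_r = 0.5,
                         delta_r = 0.15,
                         region_radius_mm = 6,
                         signal_amplitude = 1,
                         noise_sd = 1,
                         activation_center = c(-28, -16, 24),
                         activation_amplitude = 2,
                         seed = 20201119) {
  n <- nrow(region_centers)
  if (length(pairwise_r) == 1) {
    R <- matrix(pairwise_r, n, n); diag(R) <- 1
  } else R <- pairwise_r
  if (length(delta_r) == 1) {
    D <- matrix(0, n, n)
    if (n >= 2) D[1, 2] <- D[2, 1] <- delta_r
  } else D <- delta_r
  if (any(abs(R[upper.tri(R)]) >= 1))
    stop("planted correlations must lie strictly inside (-1, 1)")
  if (any(abs((R + D)[upper.tri(R)]) >= 1))
    stop("delta_r pushes a post-session correlation outside (-1, 1)")
  structure(list(region_centers = region_centers, pairwise_r = R,
                 delta_r = D, region_radius_mm = region_radius_mm,
                 signal_amplitude = signal_amplitude, noise_sd = noise_sd,
                 activation_center = activation_center,
                 activation_amplitude = activation_amplitude,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# Full-grid spatial weight of one region: 1 inside the region sphere, Gaussian
# skirt (FWHM skirt_fwhm_mm) outside, truncated at 3 sigma.
region_weights <- function(center_mm, radius_mm, affine, grid_shape,
                           skirt_fwhm_mm = 6) {
  sig <- fwhm_to_sigma(skirt_fwhm_mm)
  ijk <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3])))
  xyz <- voxel_to_mm(affine, ijk)
  d <- sqrt(rowSums(sweep(xyz, 2, center_mm)^2))
  excess <- pmax(d - radius_mm, 0)
  w <- exp(-excess^2 / (2 * sig^2))
  w[excess > 3 * sig] <- 0
  w
}

# Latent-source correlation compensating for iid-noise attenuation of the
# region-mean series, so the *observable* region-mean correlation targets the
# planted value. k = per-region voxel counts.
latent_correlation <- function(R_target, k, signal_amplitude, noise_sd) {
  lam <- 1 / sqrt(1 + noise_sd^2 / (signal_amplitude^2 * k))
  R_lat <- R_target / outer(lam, lam)
  diag(R_lat) <- 1
  if (any(abs(R_lat[upper.tri(R_lat)]) >= 1))
    stop("planted correlation unattainable at this noise level: ",
         "|latent correlation| >= 1 after attenuation compensation")
  R_lat
}

# Draw T samples of n latent sources with the given correlation matrix.
draw_sources <- function(n_volumes, R_lat) {
  C <- tryCatch(chol(R_lat),
                error = function(e) stop("latent correlation matrix is not ",
                                         "positive definite"))
  Z <- matrix(rnorm(n_volumes * ncol(R_lat)), n_volumes)
  Z %*% C
}

synth_rest_session <- function(truth, W, R_target, n_volumes, k,
                               baseline = 100) {
  R_lat <- latent_correlation(R_target, k, truth$signal_amplitude,
                              truth$noise_sd)
  S <- draw_sources(n_volumes, R_lat)            # T x nregions
  sig <- truth$signal_amplitude * (W %*% t(S))   # V x T
  sig + baseline + matrix(rnorm(length(sig), sd = truth$noise_sd),
                          nrow(sig))
}

#' Generate a paired pre/post resting-state run
#'
#' Regional signals are shared latent Gaussian sources mixed to hit the
#' planted region-mean correlations (after analytic compensation for the
#' attenuation caused by iid voxel noise averaged over the region), spread
#' spatially as a top-hat region plus Gaussian skirt, on a 100-unit baseline.
#'
#' @param truth a [ground_truth()] record.
#' @param grid_shape length-3 grid dimensions (default desk-scale 24x24x18).
#' @param n_volumes volumes per run (>= 20).
#' @param tr repetition time, seconds.
#' @param voxel_size_mm voxel edge, mm.
#' @return list with `pre` and `post`, each a [bold_image()].
#' @export
make_rest_bold <- function(truth, grid_shape = c(24, 24, 18),
                           n_volumes = 150, tr = 2, voxel_size_mm = 4) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_volumes < 20) stop("n_volumes must be at least 20")
  affine <- make_affine(voxel_size_mm, grid_shape)
  nr <- nrow(truth$region_centers)
  vox <- lapply(seq_len(nr), function(j)
    resolve_sphere(truth$region_centers[j, ], truth$region_radius_mm,
                   affine, grid_shape))
  ijk_frac <- mm_to_voxel(affine, truth$region_centers)
  if (any(ijk_frac < 1) || any(sweep(ijk_frac, 2, grid_shape) > 0))
    stop("a region centre lies outside the grid")
  k <- vapply(vox, function(v) nrow(v$ijk), integer(1))
  W <- vapply(seq_len(nr), function(j)
    region_weights(truth$region_centers[j, ], truth$region_radius_mm,
                   affine, grid_shape),
    numeric(prod(grid_shape)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(truth$seed)
  pre_mat <- synth_rest_session(truth, W, truth$pairwise_r, n_volumes, k)
  post_mat <- synth_rest_session(truth, W, truth$pairwise_r + truth$delta_r,
                                 n_volumes, k)
  to_bold <- function(m, id) bold_image(array(m, c(grid_shape, n_volumes)),
                                        tr, affine, id)
  list(pre = to_bold(pre_mat, "rest-pre"), post = to_bold(post_mat, "rest-post"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Canonical double-gamma haemodynamic response function
#'
#' Peak at 6 s, undershoot at 16 s, peak-to-undershoot ratio 6; the de facto
#' standard response shape for block and event designs.
#'
#' @param t time points in seconds.
#' @param peak_delay,undershoot_delay gamma shape parameters (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return numeric HRF values at `t`, scaled to unit peak.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             ratio = 6) {
  h <- dgamma(t, shape = peak_delay, rate = 1) -
    dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h / max(h)
}

#' Alternating task/rest block design
#'
#' @param n_volumes total number of volumes.
#' @param tr repetition time, seconds.
#' @param block_len_s block length in seconds (same for task and rest).
#' @param start first block type, `"rest"` or `"task"`.
#' @return object of class `block_design` with a 0/1 boxcar per volume.
#' @export
block_design <- function(n_volumes, tr = 2, block_len_s = 20,
                         start = "rest") {
  if (n_volumes < 2) stop("empty design")
  per_block <- max(1L, round(block_len_s / tr))
  blocks <- rep(rep(c(0, 1), length.out = ceiling(n_volumes / per_block) + 1),
                each = per_block)
  if (start == "task") blocks <- 1 - blocks
  structure(list(boxcar = blocks[seq_len(n_volumes)], tr = tr,
                 n_volumes = n_volumes, block_len_s = block_len_s),
            class = "block_design")
}

#' Expected BOLD regressor for a block design
#'
#' Boxcar convolved with the canonical double-gamma HRF at TR resolution,
#' rescaled to unit peak so amplitudes are interpretable as percent signal.
#' @param design a [block_design()].
#' @return numeric regressor, one value per volume.
#' @export
task_regressor <- function(design) {
  tt <- seq(0, 32, by = design$tr)
  h <- hrf_double_gamma(tt)
  x <- convolve(design$boxcar, rev(h), type = "open")[seq_len(design$n_volumes)]
  if (max(abs(x)) > 0) x <- x / max(abs(x))
  x
}

#' Generate a block-design task run with a planted activation locus
#'
#' @param truth a [ground_truth()] record (activation centre/amplitude used).
#' @param design a [block_design()].
#' @param grid_shape length-3 grid dimensions.
#' @param voxel_size_mm voxel edge, mm.
#' @param blob_fwhm_mm spatial extent (FWHM) of the activation blob.
#' @return a [bold_image()].
#' @export
make_task_bold <- function(truth, design, grid_shape = c(24, 24, 18),
                           voxel_size_mm = 4, blob_fwhm_mm = 6) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "block_design"))
  if (truth$activation_amplitude < 0) stop("activation amplitude must be >= 0")
  affine <- make_affine(voxel_size_mm, grid_shape)
  sig <- fwhm_to_sigma(blob_fwhm_mm)
  ijk <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3])))
  xyz <- voxel_to_mm(affine, ijk)
  d2 <- rowSums(sweep(xyz, 2, truth$activation_center)^2)
  blob <- exp(-d2 / (2 * sig^2))
  reg <- task_regressor(design)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(truth$seed, "task"))
  m <- 100 + truth$activation_amplitude * outer(blob, reg) +
    matrix(rnorm(length(blob) * design$n_volumes, sd = truth$noise_sd),
           length(blob))
  bold_image(array(m, c(grid_shape, design$n_volumes)), design$tr, affine,
             "task")
}

#' Motion trace container
#' @param params n x 6 matrix: 3 translations (mm), 3 rotations (radians).
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6)
  structure(list(params = params, n = nrow(params)), class = "motion_trace")
}

#' Generate a synthetic motion trace
#'
#' Small Gaussian jitter on all six rigid-body parameters plus optional
#' single-volume displacement spikes on the x translation.
#'
#' @param n_volumes number of volumes.
#' @param spike_times integer volume indices receiving spikes.
#' @param spike_mm spike displacement in mm (recycled over spikes).
#' @param jitter_sd_mm baseline translation jitter SD (rotations get
#'   `jitter_sd_mm / 50` radians, i.e. matched arc length at 50 mm).
#' @param seed integer seed.
#' @return a [motion_trace()].
#' @export
make_motion_trace <- function(n_volumes, spike_times = integer(0),
                              spike_mm = 2, jitter_sd_mm = 0.05,
                              seed = 20201119) {
  if (length(spike_times) &&
      (any(spike_times < 1) || any(spike_times > n_volumes)))
    stop("spike_times out of range")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p <- cbind(matrix(rnorm(3 * n_volumes, sd = jitter_sd_mm), n_volumes),
             matrix(rnorm(3 * n_volumes, sd = jitter_sd_mm / 50), n_volumes))
  if (length(spike_times))
    p[spike_times, 1] <- p[spike_times, 1] + rep_len(spike_mm,
                                                     length(spike_times))
  motion_trace(p)
}

#' Build a multi-compartment spherical head phantom
#'
#' Concentric spheres (skin, bone, CSF, GM, WM from outside in) with optional
#' nested tumor compartments embedded in the brain. Default radii approximate
#' an adult head.
#'
#' @param layer_radii_mm named, strictly decreasing radii for
#'   skin, bone, CSF, GM, WM (mm).
#' @param tumor_spec optional named list of compartments, each
#'   `list(center = c(x,y,z), radius = r)`; names drawn from
#'   edema, tumor_nonenhancing, tumor_enhancing, necrosis. Compartments must
#'   be nested in that order (any subset allowed) and lie inside the brain.
#' @param voxel_size_mm voxel edge, mm.
#' @return a [label_volume()].
#' @export
make_head_phantom <- function(layer_radii_mm = c(skin = 92, bone = 86,
                                                 CSF = 80, GM = 76, WM = 60),
                              tumor_spec = NULL, voxel_size_mm = 4) {
  r <- layer_radii_mm
  if (!all(diff(r) < 0)) stop("layer radii must be strictly decreasing")
  if (!identical(names(r), c("skin", "bone", "CSF", "GM", "WM")))
    names(r) <- c("skin", "bone", "CSF", "GM", "WM")
  n <- as.integer(ceiling(2 * r[1] / voxel_size_mm) + 3)
  shape <- rep(n, 3)
  affine <- make_affine(voxel_size_mm, shape)
  ijk <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n)))
  xyz <- voxel_to_mm(affine, ijk)
  d <- sqrt(rowSums(xyz^2))
  lab <- integer(length(d))
  lmap <- c(skin = 1L, bone = 2L, CSF = 3L, GM = 4L, WM = 5L)
  lab[d <= r["skin"]] <- lmap["skin"]
  lab[d <= r["bone"]] <- lmap["bone"]
  lab[d <= r["CSF"]] <- lmap["CSF"]
  lab[d <= r["GM"]] <- lmap["GM"]
  lab[d <= r["WM"]] <- lmap["WM"]
  if (!is.null(tumor_spec)) {
    order_names <- c("edema", "tumor_nonenhancing", "tumor_enhancing",
                     "necrosis")
    bad <- setdiff(names(tumor_spec), order_names)
    if (length(bad)) stop("unknown tumor compartment(s): ",
                          paste(bad, collapse = ", "))
    present <- order_names[order_names %in% names(tumor_spec)]
    tmap <- c(edema = 6L, tumor_nonenhancing = 7L, tumor_enhancing = 8L,
              necrosis = 9L)
    prev <- NULL
    for (nm in present) {
      cp <- tumor_spec[[nm]]
      if (sqrt(sum(cp$center^2)) + cp$radius > r["GM"])
        stop("tumor compartment '", nm, "' extends outside the brain")
      if (!is.null(prev) &&
          sqrt(sum((cp$center - prev$center)^2)) + cp$radius > prev$radius +
          1e-9)
        stop("tumor compartment '", nm, "' is not nested in its parent")
      dd <- sqrt(rowSums(sweep(xyz, 2, cp$center)^2))
      lab[dd <= cp$radius] <- tmap[nm]
      prev <- cp
    }
    lmap <- c(lmap, tmap[present])
  }
  label_volume(array(lab, shape), lmap, voxel_size_mm, affine)
}
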