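# Desk-scale study orchestration: generate a synthetic cohort, preprocess,
# derive seeds, compute pre/post connectivity, run group statistics, solve the
# phantom field model, and regress electric field against connectivity change.

#' Study configuration with defaults
#'
#' Defaults mirror the study conditions: two 5-minute resting runs at TR 2 s
#' per session, 64 SVD components for intrinsic connectivity, 8-mm LCOR
#' kernel, 6-mm seed spheres, a 2-mA 5 x 7 cm montage, and 0.009-Hz high-pass.
#' Grids are desk-scale (24 x 24 x 18 at 4 mm).
#'
#' @param ... overrides for any default field.
#' @return object of class `study_config` (a named list).
#' @export
study_config <- function(...) {
  cfg <- list(
    n_subjects = 12,
    master_seed = 20201119,
    grid_shape = c(24, 24, 18),
    voxel_size_mm = 4,
    n_volumes_per_run = 150,
    n_runs = 2,
    tr = 2,
    pairwise_r = 0.5,
    delta_r = 0.15,
    region_radius_mm = 6,
    signal_amplitude = 1,
    noise_sd = 1,
    n_compcor = 5,
    z_thresh = 5,
    fd_thresh = 0.9,
    cutoff_hz = 0.009,
    seed_source = "task_glm",        # or "ground_truth"
    seed_radius_mm = 6,
    task_n_volumes = 120,
    task_block_len_s = 20,
    glm_smooth_fwhm_mm = 6,
    n_components = 64,
    lcor_fwhm_mm = 8,
    metrics = c("interhemispheric", "ic", "lcor"),
    do_voxelwise = TRUE,
    n_perm = 500,
    voxel_p_thresh = 0.005,
    cluster_q_thresh = 0.05,
    do_efield = TRUE,
    phantom_radii = c(skin = 92, bone = 86, CSF = 80, GM = 76, WM = 60),
    phantom_radius_jitter = 4,       # per-subject skull-size variation (mm)
    phantom_voxel_mm = 6,
    montage = list(anode_polar = 45, anode_azimuth = 180,
                   cathode_polar = 80, cathode_azimuth = 105,
                   pad_mm = c(70, 50), current_A = 2e-3),
    conductivity = list(),
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "study_config")
}

#' Load a study configuration from JSON
#' @param path JSON file with any subset of [study_config()] fields.
#' @return a `study_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$phantom_radii)) raw$phantom_radii <- unlist(raw$phantom_radii)
  do.call(study_config, raw)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  derive_seed(0, as.character(s))
}

# Noise-voxel mask for aCompCor: voxels untouched by any regional signal.
pure_noise_mask <- function(truth, affine, grid_shape) {
  w <- rowSums(vapply(seq_len(nrow(truth$region_centers)), function(j)
    region_weights(truth$region_centers[j, ], truth$region_radius_mm,
                   affine, grid_shape),
    numeric(prod(grid_shape))))
  array(w == 0, grid_shape)
}

subject_truth <- function(cfg, s) {
  ground_truth(pairwise_r = cfg$pairwise_r, delta_r = cfg$delta_r,
               region_radius_mm = cfg$region_radius_mm,
               signal_amplitude = cfg$signal_amplitude,
               noise_sd = cfg$noise_sd,
               seed = derive_seed(cfg$master_seed, paste0("subject-", s)))
}

# Anatomically plausible centre boxes for peak selection (left/right halves).
allowed_mask_side <- function(affine, grid_shape, side) {
  ijk <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3])))
  x <- voxel_to_mm(affine, ijk)[, 1]
  array(if (side == "left") x < 0 else x > 0, grid_shape)
}

subject_session <- function(cfg, truth, session_bolds, motions, noise_mask,
                            seeds) {
  runs <- lapply(seq_along(session_bolds), function(r)
    preprocess_run(session_bolds[[r]], motions[[r]], noise_mask,
                   n_compcor = cfg$n_compcor, z_thresh = cfg$z_thresh,
                   fd_thresh = cfg$fd_thresh, cutoff_hz = cfg$cutoff_hz)$bold)
  bold <- concat_runs(runs)
  mask <- brain_mask(bold)
  out <- list()
  if ("interhemispheric" %in% cfg$metrics)
    out$interhemispheric_z <- interhemispheric_fc(bold, seeds$left,
                                                  seeds$right)
  if ("ic" %in% cfg$metrics) {
    ic <- intrinsic_connectivity(bold, mask, n_components = cfg$n_components)
    out$ic_left <- roi_mean(ic, seeds$left)
    out$ic_right <- roi_mean(ic, seeds$right)
    out$ic_map <- ic
  }
  if ("lcor" %in% cfg$metrics) {
    lcor <- local_correlation(bold, mask, kernel_spec(cfg$lcor_fwhm_mm))
    out$lcor_left <- roi_mean(lcor, seeds$left)
    out$lcor_right <- roi_mean(lcor, seeds$right)
    out$lcor_map <- lcor
  }
  out
}

derive_subject_seeds <- function(cfg, truth, affine, grid_shape) {
  if (cfg$seed_source == "ground_truth") {
    list(left = roi_sphere(truth$region_centers[1, ], affine, grid_shape,
                           cfg$seed_radius_mm, "left"),
         right = roi_sphere(truth$region_centers[2, ], affine, grid_shape,
                            cfg$seed_radius_mm, "right"))
  } else {
    des <- block_design(cfg$task_n_volumes, cfg$tr, cfg$task_block_len_s)
    seeds <- list()
    for (side in c("left", "right")) {
      tr_side <- truth
      tr_side$activation_center <-
        truth$region_centers[if (side == "left") 1 else 2, ]
      tr_side$seed <- derive_seed(truth$seed, paste0("task-", side))
      tb <- make_task_bold(tr_side, des, cfg$grid_shape, cfg$voxel_size_mm)
      tm <- run_block_glm(tb, des, smooth_fwhm_mm = cfg$glm_smooth_fwhm_mm,
                          cutoff_hz = cfg$cutoff_hz)
      seeds[[side]] <- pick_peak_seed(tm, allowed_mask_side(affine, grid_shape,
                                                            side),
                                      cfg$seed_radius_mm, side)
    }
    seeds
  }
}

subject_efield <- function(cfg, s) {
  jit <- (derive_seed(cfg$master_seed, paste0("phantom-", s)) %%
            1000 / 1000 - 0.5) * 2 * cfg$phantom_radius_jitter
  radii <- cfg$phantom_radii + jit
  phantom <- make_head_phantom(radii, voxel_size_mm = cfg$phantom_voxel_mm)
  mesh <- voxels_to_tetmesh(phantom)
  mont <- do.call(montage_spec, cfg$montage)
  patches <- place_electrodes(mesh, mont)
  tab <- conductivity_table(if (length(cfg$conductivity))
    unlist(cfg$conductivity) else NULL)
  sol <- solve_field(mesh, tab, patches, mont$current_A)
  ef <- efield_to_voxels(sol, phantom)
  # left-M1 stand-in: a 6-mm sphere in gray matter under the anode
  target <- mont$anode_dir * (radii["GM"] - 4)
  roi <- roi_sphere(target, phantom$affine, dim(phantom$labels),
                    cfg$seed_radius_mm, "left")
  brain <- which(phantom$labels %in%
                   phantom$label_map[c("GM", "WM")])
  list(roi_mean = roi_mean_ef(ef, roi, phantom, c("GM", "WM")),
       brain_mean = mean(ef[brain]))
}

#' Run the full desk-scale study
#'
#' Executes, in order: cohort generation, per-run denoising, seed derivation,
#' pre/post connectivity metrics, paired group statistics (with optional
#' voxel-wise permutation cluster inference on the intrinsic-connectivity
#' maps), the phantom electric-field model, and the field-vs-connectivity-
#' change regressions. Fully deterministic given the configuration: every
#' stage seed derives from the master seed.
#'
#' @param config a [study_config()].
#' @return object of class `study_report` (a nested list; see the JSON schema
#'   shipped in `inst/schema/`). Written to `config$out_dir/report.json` when
#'   an output directory is set.
#' @export
run_study <- function(config) {
  cfg <- config
  if (cfg$n_subjects < 2)
    stop("group statistics require at least 2 subjects (n >= 2)")
  affine <- make_affine(cfg$voxel_size_mm, cfg$grid_shape)
  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    truth <- subject_truth(cfg, s)
    noise_mask <- pure_noise_mask(truth, affine, cfg$grid_shape)
    seeds <- derive_subject_seeds(cfg, truth, affine, cfg$grid_shape)
    pre_runs <- list(); post_runs <- list(); motions <- list()
    for (r in seq_len(cfg$n_runs)) {
      tr_run <- truth
      tr_run$seed <- derive_seed(truth$seed, paste0("run-", r))
      rb <- make_rest_bold(tr_run, cfg$grid_shape, cfg$n_volumes_per_run,
                           cfg$tr, cfg$voxel_size_mm)
      pre_runs[[r]] <- rb$pre
      post_runs[[r]] <- rb$post
      motions[[r]] <- make_motion_trace(cfg$n_volumes_per_run,
                                        seed = derive_seed(tr_run$seed,
                                                           "motion"))
    }
    pre <- subject_session(cfg, truth, pre_runs, motions, noise_mask, seeds)
    post <- subject_session(cfg, truth, post_runs, motions, noise_mask, seeds)
    subjects[[s]] <- list(id = sprintf("sub-%02d", s), pre = pre, post = post,
                          seeds = seeds)
  }
  metric_names <- c(
    if ("interhemispheric" %in% cfg$metrics) "interhemispheric_z",
    if ("ic" %in% cfg$metrics) c("ic_left", "ic_right"),
    if ("lcor" %in% cfg$metrics) c("lcor_left", "lcor_right"))
  pull <- function(session, nm) vapply(subjects, function(su)
    su[[session]][[nm]], numeric(1))
  group <- list()
  for (nm in metric_names) {
    pre_v <- pull("pre", nm); post_v <- pull("post", nm)
    tt <- paired_t_one_tailed(pre_v, post_v)
    sw <- tryCatch(shapiro_wilk_screen(post_v - pre_v),
                   error = function(e) list(W = NA_real_, p = NA_real_))
    group[[nm]] <- list(pre = pre_v, post = post_v,
                        t = tt$t, df = tt$df, p = tt$p,
                        mean_diff = tt$mean_diff, sd_diff = tt$sd_diff,
                        shapiro_W = sw$W, shapiro_p = sw$p)
  }
  clusters <- NULL
  if (isTRUE(cfg$do_voxelwise) && "ic" %in% cfg$metrics) {
    tm <- voxelwise_paired_contrast(lapply(subjects, function(su) su$pre$ic_map),
                                    lapply(subjects, function(su) su$post$ic_map))
    cl <- cluster_inference(tm, cfg$voxel_p_thresh, cfg$cluster_q_thresh,
                            cfg$n_perm,
                            seed = derive_seed(cfg$master_seed, "clusters"))
    clusters <- cl$clusters
  }
  efield <- NULL; regressions <- NULL
  if (isTRUE(cfg$do_efield)) {
    efs <- lapply(seq_len(cfg$n_subjects), function(s) subject_efield(cfg, s))
    efield <- list(roi_mean = vapply(efs, `[[`, numeric(1), "roi_mean"),
                   brain_mean = vapply(efs, `[[`, numeric(1), "brain_mean"))
    regressions <- list()
    for (nm in intersect(c("ic_left", "ic_right", "lcor_left", "lcor_right"),
                         metric_names)) {
      delta <- pull("post", nm) - pull("pre", nm)
      rg <- simple_regression(efield$roi_mean, delta)
      regressions[[paste0("delta_", nm, "_vs_ef")]] <-
        list(slope = rg$slope, intercept = rg$intercept, r2 = rg$r2,
             t = rg$t, df = rg$df, p = rg$p)
    }
  }
  report <- structure(list(
    subjects = lapply(subjects, function(su) list(
      id = su$id,
      pre = su$pre[metric_names], post = su$post[metric_names],
      seed_left_mm = su$seeds$left$center_mm,
      seed_right_mm = su$seeds$right$center_mm)),
    group = group,
    clusters = clusters,
    efield = efield,
    regressions = regressions,
    provenance = list(config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
                      config_hash = config_hash(cfg),
                      master_seed = cfg$master_seed,
                      package_version =
                        as.character(utils::packageVersion("tdcsfc")),
                      r_version = R.version.string)),
    class = "study_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(cfg$out_dir, "report.json"))
  }
  report
}

#' Write a study report as JSON
#' @param report a `study_report`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Check a study report against the shipped schema's required structure
#' @param report a `study_report` or a list read back from report JSON.
#' @return TRUE invisibly; errors describe the first missing field.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema",
                                            "study_report.schema.json",
                                            package = "tdcsfc"))
  need <- unlist(schema$required)
  miss <- setdiff(need, names(report))
  if (length(miss)) stop("report is missing field(s): ",
                         paste(miss, collapse = ", "))
  gneed <- unlist(schema$properties$group$required)
  miss <- setdiff(gneed, names(report$group))
  if (length(miss)) stop("report$group is missing: ",
                         paste(miss, collapse = ", "))
  invisible(TRUE)
}
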