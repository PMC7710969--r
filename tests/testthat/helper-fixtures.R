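# Shared fixtures, built in code at test time.

# Smallest grid that holds the default +/-28 mm region centres at 4 mm voxels.
small_grid <- c(16L, 16L, 14L)

# A bold_image from an explicit voxel x time matrix on a tiny grid.
bold_from_matrix <- function(mat, grid, tr = 2, voxel_mm = 4) {
  bold_image(array(mat, c(grid, ncol(mat))), tr,
             make_affine(voxel_mm, grid))
}

random_bold <- function(grid = c(6, 6, 4), nt = 40, seed = 1, voxel_mm = 4) {
  set.seed(seed)
  bold_from_matrix(matrix(rnorm(prod(grid) * nt), prod(grid), nt),
                   grid, voxel_mm = voxel_mm)
}

# Homogeneous all-GM sphere label volume (single tissue).
gm_sphere <- function(radius_mm, voxel_mm) {
  ph <- make_head_phantom(c(skin = radius_mm, bone = radius_mm - 1e-3,
                            CSF = radius_mm - 2e-3, GM = radius_mm - 3e-3,
                            WM = radius_mm / 4),
                          voxel_size_mm = voxel_mm)
  l <- ph$labels
  l[l > 0] <- 4L
  label_volume(array(l, dim(l)), c(GM = 4L), voxel_mm, ph$affine)
}

# Antipodal small-pad montage along +/-z-tilted axis for sphere tests.
antipodal_montage <- function(pad_mm = c(10, 10), current_A = 2e-3) {
  montage_spec(anode_polar = 45, anode_azimuth = 180,
               cathode_polar = 135, cathode_azimuth = 0,
               pad_mm = pad_mm, current_A = current_A)
}

# conn_map pairs from a voxel x subject matrix of differences (pre = 0).
maps_from_diffs <- function(D, grid, affine = make_affine(4, grid)) {
  mask <- array(TRUE, grid)
  pre <- lapply(seq_len(ncol(D)), function(i)
    conn_map(rep(0, nrow(D)), mask, "IC", affine))
  post <- lapply(seq_len(ncol(D)), function(i)
    conn_map(D[, i], mask, "IC", affine))
  list(pre = pre, post = post)
}
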