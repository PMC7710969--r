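# Finite-element field model: meshing, electrodes, solver, analytic oracle.

test_that("a single voxel meshes into five conforming tetrahedra", {
  lab <- label_volume(array(4L, c(1, 1, 1)), c(GM = 4L), 3)
  mesh <- voxels_to_tetmesh(lab)
  expect_equal(nrow(mesh$elems), 5)
  expect_equal(nrow(mesh$nodes), 8)
  expect_equal(sum(mesh$volumes), 27, tolerance = 1e-12)
  expect_true(all(mesh$volumes > 0))          # orientation fixed
  # all 8 cube corners used; faces: 4 per tet, interior faces shared by 2
  ef <- element_faces(mesh$elems)
  key <- paste(ef$faces[, 1], ef$faces[, 2], ef$faces[, 3])
  counts <- table(key)
  expect_true(all(counts %in% c(1, 2)))
  expect_equal(nrow(boundary_faces(mesh)$faces), 12)   # 2 triangles x 6 faces
})

test_that("neighbouring voxels mesh conformingly via parity mirroring", {
  lab <- label_volume(array(4L, c(2, 2, 2)), c(GM = 4L), 2)
  mesh <- voxels_to_tetmesh(lab)
  expect_equal(nrow(mesh$elems), 40)
  expect_equal(sum(mesh$volumes), 8 * 8, tolerance = 1e-12)
  expect_true(all(mesh$volumes > 0))
  ef <- element_faces(mesh$elems)
  counts <- table(paste(ef$faces[, 1], ef$faces[, 2], ef$faces[, 3]))
  # conforming mesh: every face belongs to exactly 1 (surface) or 2 elements;
  # non-conforming parity would leave diagonal faces unmatched inside
  expect_true(all(counts %in% c(1, 2)))
  expect_equal(sum(counts == 1), nrow(boundary_faces(mesh)$faces))
  expect_equal(nrow(boundary_faces(mesh)$faces), 2 * 4 * 6)
})

test_that("conductivity table carries defaults and validates overrides", {
  tab <- conductivity_table()
  expect_equal(unname(tab["GM"]), 0.276)
  expect_equal(unname(tab["WM"]), 0.126)
  expect_equal(unname(tab["CSF"]), 1.65)
  tab2 <- conductivity_table(c(GM = 0.3))
  expect_equal(unname(tab2["GM"]), 0.3)
  expect_equal(unname(tab2["WM"]), 0.126)
  expect_error(conductivity_table(c(jelly = 1)), "unknown tissue")
  expect_error(conductivity_table(c(GM = -1)), "positive")
})

test_that("electrode pads land where requested with sane areas", {
  lab <- gm_sphere(20, 2.5)
  mesh <- voxels_to_tetmesh(lab)
  mont <- antipodal_montage(pad_mm = c(10, 10))
  pads <- place_electrodes(mesh, mont)
  # projected area corrects staircase inflation: <= raw, near the nominal pad
  for (p in pads) {
    expect_lte(p$area_projected, p$area_raw + 1e-9)
    expect_lt(abs(p$area_projected - 100) / 100, 0.6)  # coarse surface
    expect_gt(length(p$nodes), 3)
  }
  expect_length(intersect(pads$anode$nodes, pads$cathode$nodes), 0)
  # pad centroids sit along the montage directions on the scalp
  ca <- pads$anode$centroid / sqrt(sum(pads$anode$centroid^2))
  ck <- pads$cathode$centroid / sqrt(sum(pads$cathode$centroid^2))
  expect_gt(sum(ca * mont$anode_dir), 0.97)
  expect_gt(sum(ck * mont$cathode_dir), 0.97)
  expect_lt(sum(ca * ck), -0.9)                         # antipodal
  expect_error(place_electrodes(mesh, montage_spec(anode_polar = 45,
                                                   anode_azimuth = 180,
                                                   cathode_polar = 46,
                                                   cathode_azimuth = 180,
                                                   pad_mm = c(40, 40))),
               "overlap")
})

test_that("analytic sphere potential has the expected symmetries", {
  R <- 50; sig <- 0.3
  src <- c(0, 0, R); snk <- c(0, 0, -R)
  set.seed(19)
  probes <- matrix(runif(30, -0.6 * R, 0.6 * R), 10, 3)
  v <- apply(probes, 1, analytic_sphere_potential, src, snk, sig, R)
  # antisymmetry under probe inversion (electrodes swap roles)
  v_neg <- apply(-probes, 1, analytic_sphere_potential, src, snk, sig, R)
  expect_equal(v_neg, -v, tolerance = 1e-8)
  # scales as 1/sigma and linearly in current
  v2 <- apply(probes, 1, analytic_sphere_potential, src, snk, 2 * sig, R)
  expect_equal(v2, v / 2, tolerance = 1e-10)
  v3 <- apply(probes, 1, analytic_sphere_potential, src, snk, sig, R,
              current_A = 4e-3)
  expect_equal(v3, 2 * v, tolerance = 1e-10)
  # equatorial plane is at zero potential
  expect_lt(abs(analytic_sphere_potential(c(20, 13, 0), src, snk, sig, R)),
            1e-8)
  # truncation is stable: generous cap changes nothing
  p <- c(5, -8, 22)
  expect_equal(analytic_sphere_potential(p, src, snk, sig, R),
               analytic_sphere_potential(p, src, snk, sig, R,
                                         max_terms = 20000),
               tolerance = 1e-9)
  expect_error(analytic_sphere_potential(c(0, 0, R), src, snk, sig, R),
               "inside")
})

test_that("FEM solution on a homogeneous sphere behaves physically", {
  lab <- gm_sphere(20, 2.5)
  mesh <- voxels_to_tetmesh(lab)
  mont <- antipodal_montage(pad_mm = c(10, 10), current_A = 2e-3)
  pads <- place_electrodes(mesh, mont)
  tab <- conductivity_table()
  sol <- solve_field(mesh, tab, pads, current_A = mont$current_A)
  expect_lt(sol$residual, 1e-8)
  # Dirichlet nodes clamped
  expect_true(all(sol$V[pads$cathode$nodes] == 0))
  expect_true(all(is.finite(sol$Emag)))
  # exact linearity in the injected current
  sol2 <- solve_field(mesh, tab, pads, current_A = 2 * mont$current_A)
  expect_equal(sol2$V, 2 * sol$V, tolerance = 1e-9)
  expect_equal(sol2$Emag, 2 * sol$Emag, tolerance = 1e-9)
  # exact 1/sigma scaling for a homogeneous medium
  sol3 <- solve_field(mesh, conductivity_table(c(GM = 2 * tab[["GM"]])),
                      pads, current_A = mont$current_A)
  expect_equal(sol3$V, sol$V / 2, tolerance = 1e-9)
  # swapping anode and cathode leaves the interior field magnitude intact
  flip <- list(anode = pads$cathode, cathode = pads$anode)
  solf <- solve_field(mesh, tab, flip, current_A = mont$current_A)
  cent <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
             mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  interior <- sqrt(rowSums(cent^2)) < 12
  expect_equal(mean(solf$Emag[interior]), mean(sol$Emag[interior]),
               tolerance = 0.05)
  # discrete current conservation through the equatorial plane
  cut <- dim(lab$labels)[3] %/% 2
  I_cross <- flux_through_plane(sol, cut, axis = 3)
  expect_lt(abs(abs(I_cross) - mont$current_A) / mont$current_A, 0.01)
})

test_that("FEM potentials match the analytic series oracle", {
  lab <- gm_sphere(24, 2)
  mesh <- voxels_to_tetmesh(lab)
  mont <- antipodal_montage(pad_mm = c(8, 8), current_A = 2e-3)
  pads <- place_electrodes(mesh, mont)
  sig <- 0.3
  sol <- solve_field(mesh, conductivity_table(c(GM = sig)), pads,
                     current_A = mont$current_A)
  # probe along the electrode axis and off-axis, away from the surface
  axis <- mont$anode_dir
  perp <- c(axis[2], -axis[1], 0); perp <- perp / sqrt(sum(perp^2))
  probes <- rbind(8 * axis, -8 * axis, 12 * axis, 10 * perp,
                  6 * axis + 8 * perp, c(0.3, 0.2, 0.1))
  Rfit <- 24
  v_fem <- interpolate_potential(sol, probes)
  v_an <- apply(probes, 1, analytic_sphere_potential,
                Rfit * axis, -Rfit * axis, sig, Rfit,
                current_A = mont$current_A)
  # the FEM gauge (V = 0 on the cathode pad) differs from the analytic gauge
  # by a constant; compare after removing the mean offset
  off <- mean(v_fem - v_an)
  expect_lt(max(abs(v_fem - v_an - off)) / max(abs(v_an)), 0.08)
})

test_that("voxelised field maps and ROI means are consistent", {
  lab <- gm_sphere(16, 2.5)
  mesh <- voxels_to_tetmesh(lab)
  pads <- place_electrodes(mesh, antipodal_montage(pad_mm = c(8, 8)))
  sol <- solve_field(mesh, conductivity_table(), pads)
  ef <- efield_to_voxels(sol, lab)
  inside <- lab$labels > 0
  expect_true(all(is.finite(ef[inside])))
  expect_true(all(is.na(ef[!inside])))
  # voxel value is the volume-weighted mean of its elements' |E|
  v1 <- which(inside)[1]
  sel <- mesh$elem_voxel == v1
  expect_equal(ef[v1], sum(sol$Emag[sel] * mesh$volumes[sel]) /
                 sum(mesh$volumes[sel]), tolerance = 1e-12)
  # roi_mean_ef averages the map over the sphere ROI, honouring tissue masks
  roi <- roi_sphere(c(0, 0, 0), lab$affine, dim(lab$labels), 6)
  m1 <- roi_mean_ef(ef, roi)
  expect_equal(m1, mean(ef[roi$voxel_set$linear]), tolerance = 1e-12)
  expect_equal(roi_mean_ef(ef, roi, lab, tissues = "GM"), m1)
  expect_error(roi_mean_ef(ef, roi, lab, tissues = "WM"), "empty ROI")
})

test_that("a high-conductivity inclusion shunts current around itself", {
  # replace a central ball with CSF-like conductivity: the field inside the
  # inclusion drops, because J stays bounded while sigma rises
  lab <- gm_sphere(16, 2.5)
  d <- dim(lab$labels)
  ijk <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  xyz <- voxel_to_mm(lab$affine, ijk)
  ball <- sqrt(rowSums(xyz^2)) <= 5
  lab2 <- lab
  lab2$labels[ball & lab$labels > 0] <- 3L
  lab2$label_map <- c(GM = 4L, CSF = 3L)
  mesh1 <- voxels_to_tetmesh(lab)
  mesh2 <- voxels_to_tetmesh(lab2)
  mont <- antipodal_montage(pad_mm = c(8, 8))
  sol1 <- solve_field(mesh1, conductivity_table(),
                      place_electrodes(mesh1, mont))
  sol2 <- solve_field(mesh2, conductivity_table(),
                      place_electrodes(mesh2, mont))
  ef1 <- efield_to_voxels(sol1, lab)
  ef2 <- efield_to_voxels(sol2, lab2)
  core <- ball & lab$labels > 0
  expect_lt(mean(ef2[core]), 0.7 * mean(ef1[core]))
})
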