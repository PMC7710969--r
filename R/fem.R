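# Phantom-specific tDCS electric-field model: labelled volume -> conforming
# 5-tet-per-voxel tetrahedral mesh -> per-tissue conductivity -> P1 FEM solve
# of div(sigma grad V) = 0 with current-density (anode) and grounded-patch
# (cathode) boundary conditions -> per-element fields, voxel |E| maps and ROI
# means. An analytic conducting-sphere series solution serves as oracle.

#' Default tissue conductivities (S/m)
#'
#' Healthy-tissue values follow the conventions of volumetric tDCS modelling
#' pipelines; tumor compartments use published estimates for enhancing tumor,
#' non-enhancing tumor, necrosis, and edema.
#'
#' @return named numeric vector, tissue name -> sigma in S/m.
#' @export
conductivity_defaults <- function() {
  c(WM = 0.126, GM = 0.276, CSF = 1.65, bone = 0.01, skin = 0.465,
    air = 2.5e-14, gel = 0.3, electrode = 5.9e7,
    tumor_enhancing = 0.170, tumor_nonenhancing = 0.332,
    necrosis = 1.0, edema = 1.185)
}

#' Conductivity table with validation
#' @param values named numeric vector (tissue -> S/m) overriding defaults.
#' @return named numeric vector; all entries positive.
#' @export
conductivity_table <- function(values = NULL) {
  tab <- conductivity_defaults()
  if (!is.null(values)) {
    bad <- setdiff(names(values), tissue_vocabulary())
    if (length(bad)) stop("unknown tissue(s): ", paste(bad, collapse = ", "))
    tab[names(values)] <- values
  }
  if (any(tab <= 0)) stop("all conductivities must be positive")
  tab
}

#' Electrode montage specification
#'
#' Pad positions are angular coordinates on the phantom scalp: polar angle
#' from the vertex (+z) and azimuth measured from +x towards +y, both in
#' degrees. Defaults approximate an anode over the left motor cortex (C3-like)
#' and a cathode over the right forehead (FP1-like), 5 x 7 cm pads, 2 mA.
#'
#' @param anode_polar,anode_azimuth anode centre angles (degrees).
#' @param cathode_polar,cathode_azimuth cathode centre angles (degrees).
#' @param pad_mm pad dimensions c(length, width) in mm (default 70 x 50).
#' @param current_A injected current in amperes (default 2e-3).
#' @return object of class `montage_spec`.
#' @export
montage_spec <- function(anode_polar = 45, anode_azimuth = 180,
                         cathode_polar = 80, cathode_azimuth = 105,
                         pad_mm = c(70, 50), current_A = 2e-3) {
  if (!(current_A > 0)) stop("current must be positive")
  dir_of <- function(pol, az) {
    p <- pol * pi / 180; a <- az * pi / 180
    c(sin(p) * cos(a), sin(p) * sin(a), cos(p))
  }
  structure(list(anode_dir = dir_of(anode_polar, anode_azimuth),
                 cathode_dir = dir_of(cathode_polar, cathode_azimuth),
                 pad_mm = pad_mm, current_A = current_A),
            class = "montage_spec")
}

# vectorised cross product for n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Corner patterns of the two mirrored 5-tet decompositions of a cube.
# Corners are numbered b = di + 2*dj + 4*dk, di/dj/dk in {0,1}.
five_tet_patterns <- function() {
  even <- rbind(c(0, 1, 2, 4), c(3, 1, 7, 2), c(5, 1, 4, 7),
                c(6, 2, 7, 4), c(1, 2, 4, 7))
  # mirror in x: XOR each corner with 1
  odd <- matrix(bitwXor(even, 1L), nrow(even))
  list(even = even, odd = odd)
}

#' Tetrahedralise a labelled voxel volume
#'
#' Each labelled voxel is split into 5 tetrahedra; the decomposition is
#' mirrored on alternating voxel parity so faces shared between neighbouring
#' voxels conform. Element volumes sum exactly to the labelled voxel volume
#' and every element inherits its voxel's tissue label.
#'
#' @param labels a [label_volume()].
#' @return object of class `tet_mesh`: `nodes` (n x 3, mm), `elems` (m x 4
#'   node indices, positively oriented), `elem_label` (integer tissue label),
#'   `elem_voxel` (linear index of the source voxel), `label_map`, `affine`,
#'   `grid_shape`, `volumes` (element volumes, mm^3).
#' @export
voxels_to_tetmesh <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$labels)
  vox <- which(labels$labels > 0)
  if (!length(vox)) stop("empty labelled volume")
  ijk <- arrayInd(vox, d)                      # 1-based voxel indices
  # corner-grid node ids (0-based corners, dims d+1)
  nd <- d + 1L
  corner_id <- function(ci, cj, ck) ci + cj * nd[1] + ck * nd[1] * nd[2] + 1
  corners <- matrix(0L, length(vox), 8)        # columns = corner code b
  for (b in 0:7) {
    di <- bitwAnd(b, 1L); dj <- bitwAnd(bitwShiftR(b, 1L), 1L)
    dk <- bitwAnd(bitwShiftR(b, 2L), 1L)
    corners[, b + 1] <- corner_id(ijk[, 1] - 1L + di, ijk[, 2] - 1L + dj,
                                  ijk[, 3] - 1L + dk)
  }
  pat <- five_tet_patterns()
  parity <- (ijk[, 1] + ijk[, 2] + ijk[, 3]) %% 2L
  build <- function(rows, pattern) {
    if (!length(rows)) return(NULL)
    do.call(rbind, lapply(seq_len(5), function(tt)
      cbind(corners[rows, pattern[tt, 1] + 1], corners[rows, pattern[tt, 2] + 1],
            corners[rows, pattern[tt, 3] + 1], corners[rows, pattern[tt, 4] + 1],
            rows)))
  }
  elems_raw <- rbind(build(which(parity == 0L), pat$even),
                     build(which(parity == 1L), pat$odd))
  src <- elems_raw[, 5]
  elems <- elems_raw[, 1:4, drop = FALSE]
  used <- sort(unique(as.vector(elems)))
  remap <- integer(prod(nd)); remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], ncol = 4)
  # node coordinates: corner (ci,cj,ck) sits at 0-based voxel coord c - 0.5
  cijk <- arrayInd(used, nd) - 1L
  nodes <- voxel_to_mm(labels$affine, cijk + 0.5)  # voxel_to_mm subtracts 1
  # positive orientation
  p1 <- nodes[elems[, 1], , drop = FALSE]
  a <- nodes[elems[, 2], , drop = FALSE] - p1
  b <- nodes[elems[, 3], , drop = FALSE] - p1
  cc <- nodes[elems[, 4], , drop = FALSE] - p1
  det <- rowSums(a * cross3(b, cc))
  neg <- det < 0
  if (any(neg)) {
    tmp <- elems[neg, 2]; elems[neg, 2] <- elems[neg, 3]; elems[neg, 3] <- tmp
    det[neg] <- -det[neg]
  }
  structure(list(nodes = nodes, elems = elems,
                 elem_label = as.integer(labels$labels[vox][src]),
                 elem_voxel = vox[src],
                 label_map = labels$label_map, affine = labels$affine,
                 grid_shape = d, voxel_size_mm = labels$voxel_size_mm,
                 volumes = det / 6),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh: %d nodes, %d tetrahedra, %.4g mm^3 total>\n",
              nrow(x$nodes), nrow(x$elems), sum(x$volumes)))
  invisible(x)
}

# All element faces, as sorted node triples, with the owning element.
element_faces <- function(elems) {
  opp <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  f <- do.call(rbind, lapply(1:4, function(i) elems[, opp[i, ], drop = FALSE]))
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  list(faces = cbind(lo, f[, 1] + f[, 2] + f[, 3] - lo - hi, hi),
       elem = rep(seq_len(nrow(elems)), 4))
}

#' Boundary faces of a tetrahedral mesh
#'
#' Faces belonging to exactly one element (the mesh surface).
#' @param mesh a `tet_mesh`.
#' @return list: `faces` (k x 3 node triples), `elem` (owning element index).
#' @export
boundary_faces <- function(mesh) {
  ef <- element_faces(mesh$elems)
  o <- do.call(order, as.data.frame(ef$faces))
  f <- ef$faces[o, , drop = FALSE]
  same_next <- c(rowSums(f[-nrow(f), , drop = FALSE] ==
                           f[-1, , drop = FALSE]) == 3, FALSE)
  same_prev <- c(FALSE, head(same_next, -1))
  single <- !(same_next | same_prev)
  list(faces = f[single, , drop = FALSE], elem = ef$elem[o][single])
}

face_geometry <- function(mesh, faces) {
  p1 <- mesh$nodes[faces[, 1], , drop = FALSE]
  p2 <- mesh$nodes[faces[, 2], , drop = FALSE]
  p3 <- mesh$nodes[faces[, 3], , drop = FALSE]
  n <- cross3(p2 - p1, p3 - p1)
  area <- 0.5 * sqrt(rowSums(n^2))
  centroid <- (p1 + p2 + p3) / 3
  list(area = area, centroid = centroid, normal = n / (2 * area))
}

#' Place electrode pads on the phantom scalp
#'
#' Selects boundary faces whose centroids fall inside a geodesic rectangle of
#' the pad dimensions around each montage position. Reported `area_projected`
#' projects each face onto the local tangent plane, correcting the staircase
#' inflation of a voxelised surface; `area_raw` is the bare triangle sum.
#'
#' @param mesh a `tet_mesh` (phantom centred at the mm origin).
#' @param montage a [montage_spec()].
#' @return list with `anode` and `cathode`, each containing `faces`
#'   (node triples), `area_raw`, `area_projected` (mm^2), and `nodes`.
#' @export
place_electrodes <- function(mesh, montage) {
  bf <- boundary_faces(mesh)
  if (!nrow(bf$faces)) stop("scalp surface not extractable")
  g <- face_geometry(mesh, bf$faces)
  rad <- sqrt(rowSums(g$centroid^2))
  rhat <- g$centroid / rad
  pick <- function(dirv, pad) {
    dirv <- dirv / sqrt(sum(dirv^2))
    e1 <- c(dirv[3], 0, -dirv[1])              # tangent, in the x-z plane
    if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(dirv[2] * e1[3] - dirv[3] * e1[2],
            dirv[3] * e1[1] - dirv[1] * e1[3],
            dirv[1] * e1[2] - dirv[2] * e1[1])
    cosg <- pmin(pmax(rhat %*% dirv, -1), 1)
    gam <- acos(as.vector(cosg))
    gd <- gam * rad                            # geodesic distance (mm)
    az <- atan2(as.vector(rhat %*% e2), as.vector(rhat %*% e1))
    u <- gd * cos(az); v <- gd * sin(az)
    which(abs(u) <= pad[1] / 2 & abs(v) <= pad[2] / 2)
  }
  ai <- pick(montage$anode_dir, montage$pad_mm)
  ci <- pick(montage$cathode_dir, montage$pad_mm)
  if (!length(ai) || !length(ci)) stop("pad does not intersect the scalp")
  if (length(intersect(ai, ci))) stop("electrode pads overlap on the scalp")
  mk <- function(sel) {
    proj <- abs(rowSums(g$normal[sel, , drop = FALSE] *
                          rhat[sel, , drop = FALSE]))
    list(faces = bf$faces[sel, , drop = FALSE],
         elem = bf$elem[sel],
         area_raw = sum(g$area[sel]),
         area_projected = sum(g$area[sel] * proj),
         nodes = sort(unique(as.vector(bf$faces[sel, ]))),
         centroid = colSums(g$centroid[sel, , drop = FALSE] * g$area[sel]) /
           sum(g$area[sel]))
  }
  out <- list(anode = mk(ai), cathode = mk(ci))
  if (length(intersect(out$anode$nodes, out$cathode$nodes)))
    stop("electrode pads share mesh nodes; move them apart")
  out
}

# Per-element P1 basis gradients (1/m) and volumes (m^3); nodes in mm.
element_gradients <- function(mesh) {
  P <- mesh$nodes / 1000                       # metres
  p1 <- P[mesh$elems[, 1], , drop = FALSE]
  a <- P[mesh$elems[, 2], , drop = FALSE] - p1
  b <- P[mesh$elems[, 3], , drop = FALSE] - p1
  cc <- P[mesh$elems[, 4], , drop = FALSE] - p1
  det <- rowSums(a * cross3(b, cc))
  g2 <- cross3(b, cc) / det
  g3 <- cross3(cc, a) / det
  g4 <- cross3(a, b) / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = det / 6)
}

#' Solve the tDCS forward problem on a labelled mesh
#'
#' Piecewise-linear finite elements for div(sigma grad V) = 0 with a uniform
#' inward current density over the anode faces (natural boundary condition),
#' V = 0 on the cathode patch (Dirichlet gauge), and zero flux elsewhere.
#' The symmetric positive-definite reduced system is solved by sparse
#' Cholesky factorisation; the relative residual is checked against 1e-8.
#'
#' @param mesh a `tet_mesh`.
#' @param table conductivity table from [conductivity_table()].
#' @param patches electrode patches from [place_electrodes()].
#' @param current_A injected current in amperes.
#' @return object of class `fem_solution`: nodal `V` (volts), per-element
#'   field `E` (V/m) and magnitude `Emag`, `current_A`, plus the mesh and
#'   patches.
#' @export
solve_field <- function(mesh, table, patches, current_A = 2e-3) {
  tiss <- names(mesh$label_map)[match(mesh$elem_label, mesh$label_map)]
  if (any(is.na(tiss)) || !all(tiss %in% names(table)))
    stop("mesh contains labels without a conductivity entry")
  sigma <- unname(table[tiss])
  eg <- element_gradients(mesh)
  sv <- sigma * eg$vol
  nn <- nrow(mesh$nodes)
  ii <- jj <- xx <- vector("list", 16)
  kk <- 1
  for (i in 1:4) for (j in 1:4) {
    ii[[kk]] <- mesh$elems[, i]
    jj[[kk]] <- mesh$elems[, j]
    xx[[kk]] <- sv * rowSums(eg$g[[i]] * eg$g[[j]])
    kk <- kk + 1
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nn, nn))
  # anode load: uniform current density over the pad, lumped per face node
  fa <- patches$anode
  gA <- face_geometry(mesh, fa$faces)
  dens <- current_A / sum(gA$area)             # A / mm^2
  f <- numeric(nn)
  for (v in 1:3) {
    tabsum <- rowsum(dens * gA$area / 3, fa$faces[, v])
    at <- as.integer(rownames(tabsum))
    f[at] <- f[at] + tabsum[, 1]
  }
  dir_nodes <- patches$cathode$nodes
  if (!length(dir_nodes)) stop("no cathode nodes: singular system")
  free <- setdiff(seq_len(nn), dir_nodes)
  Kff <- Matrix::forceSymmetric(K[free, free])
  ch <- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE)
  Vfree <- as.vector(Matrix::solve(ch, f[free], system = "A"))
  res <- sqrt(sum((as.vector(Kff %*% Vfree) - f[free])^2)) /
    max(sqrt(sum(f[free]^2)), .Machine$double.xmin)
  if (res > 1e-8) stop(sprintf("solver did not converge: relative residual %.2e", res))
  V <- numeric(nn)
  V[free] <- Vfree
  # per-element constant field E = -sum_i V_i grad(lambda_i)
  E <- -(V[mesh$elems[, 1]] * eg$g[[1]] + V[mesh$elems[, 2]] * eg$g[[2]] +
           V[mesh$elems[, 3]] * eg$g[[3]] + V[mesh$elems[, 4]] * eg$g[[4]])
  structure(list(V = V, E = E, Emag = sqrt(rowSums(E^2)),
                 current_A = current_A, mesh = mesh, patches = patches,
                 residual = res, sigma = sigma),
            class = "fem_solution")
}

#' Analytic potential in a homogeneous conducting sphere
#'
#' Legendre-series solution for a homogeneous sphere (insulated except for a
#' surface point current source and sink):
#' V(p) = I / (4 pi sigma R) * sum_n (2n+1)/n * (r/R)^n *
#' (P_n(cos gamma_source) - P_n(cos gamma_sink)). Series truncated when the
#' last term falls below 1e-10 of the running sum.
#'
#' @param probe_mm probe location (mm), strictly inside the sphere.
#' @param source_pos,sink_pos electrode positions on the surface (mm).
#' @param sigma conductivity (S/m).
#' @param radius_mm sphere radius (mm).
#' @param current_A injected current (A).
#' @param max_terms truncation cap.
#' @return potential in volts.
#' @export
analytic_sphere_potential <- function(probe_mm, source_pos, sink_pos, sigma,
                                      radius_mm, current_A = 2e-3,
                                      max_terms = 5000) {
  r <- sqrt(sum(probe_mm^2))
  if (r >= radius_mm) stop("probe must lie strictly inside the sphere")
  rho <- r / radius_mm
  cs <- if (r > 0) sum(probe_mm * source_pos) /
    (r * sqrt(sum(source_pos^2))) else 1
  ck <- if (r > 0) sum(probe_mm * sink_pos) /
    (r * sqrt(sum(sink_pos^2))) else 1
  # Legendre recurrences
  Ps0 <- 1; Ps1 <- cs; Pk0 <- 1; Pk1 <- ck
  total <- 0; rn <- 1
  stable <- 0
  for (n in seq_len(max_terms)) {
    rn <- rn * rho
    term <- (2 * n + 1) / n * rn * (Ps1 - Pk1)
    total <- total + term
    if (abs(term) < 1e-10 * max(abs(total), 1e-300)) {
      stable <- stable + 1
      if (stable >= 5) break
    } else stable <- 0
    Ps2 <- ((2 * n + 1) * cs * Ps1 - n * Ps0) / (n + 1)
    Pk2 <- ((2 * n + 1) * ck * Pk1 - n * Pk0) / (n + 1)
    Ps0 <- Ps1; Ps1 <- Ps2; Pk0 <- Pk1; Pk1 <- Pk2
    if (n == max_terms) stop("series did not converge at this probe")
  }
  current_A / (4 * pi * sigma * (radius_mm / 1000)) * total
}

#' Interpolate nodal potentials at arbitrary points
#' @param solution a `fem_solution`.
#' @param points_mm n x 3 matrix of probe locations.
#' @return numeric potentials (volts); NA outside the mesh.
#' @export
interpolate_potential <- function(solution, points_mm) {
  mesh <- solution$mesh
  points_mm <- rbind(points_mm)
  out <- rep(NA_real_, nrow(points_mm))
  vij <- mm_to_voxel(mesh$affine, points_mm)
  for (p in seq_len(nrow(points_mm))) {
    ijk <- round(vij[p, ])
    if (any(ijk < 1) || any(ijk > mesh$grid_shape)) next
    lin <- ijk[1] + (ijk[2] - 1) * mesh$grid_shape[1] +
      (ijk[3] - 1) * prod(mesh$grid_shape[1:2])
    cand <- which(mesh$elem_voxel == lin)
    for (e in cand) {
      vid <- mesh$elems[e, ]
      p1 <- mesh$nodes[vid[1], ]
      M <- t(mesh$nodes[vid[2:4], , drop = FALSE]) - p1
      lam <- tryCatch(solve(M, points_mm[p, ] - p1), error = function(e) NULL)
      if (is.null(lam)) next
      l <- c(1 - sum(lam), lam)
      if (all(l >= -1e-9)) {
        out[p] <- sum(l * solution$V[vid])
        break
      }
    }
  }
  out
}

#' Map per-element field magnitudes to a voxel volume
#'
#' Each labelled voxel's value is the volume-weighted mean of the |E| of its
#' five tetrahedra.
#'
#' @param solution a `fem_solution`.
#' @param labels the [label_volume()] the mesh was built from.
#' @return 3D array of |E| (V/m), NA outside the labelled region.
#' @export
efield_to_voxels <- function(solution, labels) {
  mesh <- solution$mesh
  if (!identical(dim(labels$labels), mesh$grid_shape))
    stop("label volume does not match the mesh grid")
  wsum <- rowsum(solution$Emag * mesh$volumes, mesh$elem_voxel)
  vsum <- rowsum(mesh$volumes, mesh$elem_voxel)
  out <- array(NA_real_, dim(labels$labels))
  out[as.integer(rownames(wsum))] <- wsum[, 1] / vsum[, 1]
  out
}

#' Mean electric-field magnitude in an ROI
#'
#' @param ef_volume 3D |E| array from [efield_to_voxels()].
#' @param roi a [roi_sphere()].
#' @param labels optional [label_volume()]; with `tissues`, restricts the
#'   average to voxels of those tissue classes.
#' @param tissues character tissue names (default: brain classes).
#' @return mean |E| in V/m over the selected ROI voxels.
#' @export
roi_mean_ef <- function(ef_volume, roi, labels = NULL,
                        tissues = c("GM", "WM", "tumor_enhancing",
                                    "tumor_nonenhancing", "necrosis",
                                    "edema")) {
  idx <- roi$voxel_set$linear
  idx <- idx[is.finite(ef_volume[idx])]
  if (!is.null(labels)) {
    keep <- labels$label_map[names(labels$label_map) %in% tissues]
    idx <- idx[labels$labels[idx] %in% keep]
  }
  if (!length(idx)) stop("empty ROI after masking")
  mean(ef_volume[idx])
}

#' Net current through an axial cut plane
#'
#' Sums sigma * E . n over the element faces lying on the corner plane between
#' voxel layers `cut_after` and `cut_after + 1` along the given axis,
#' averaging the one-sided estimates from the elements below and above the
#' plane. Used to audit discrete current conservation.
#'
#' @param solution a `fem_solution`.
#' @param cut_after 1-based voxel layer index; the plane sits at its far face.
#' @param axis 1, 2 or 3.
#' @return estimated current (A) crossing the plane in the +axis direction.
#' @export
flux_through_plane <- function(solution, cut_after, axis = 3) {
  mesh <- solution$mesh
  # mm coordinate of the corner plane
  step <- mesh$voxel_size_mm[axis]
  origin <- mesh$affine[axis, 4]               # mm of voxel index 0 (0-based)
  z0 <- origin + (cut_after - 0.5) * step
  on_plane <- abs(mesh$nodes[, axis] - z0) < step * 1e-6
  opp <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  total <- c(below = 0, above = 0)
  for (fi in 1:4) {
    tri <- mesh$elems[, opp[fi, ], drop = FALSE]
    flat <- on_plane[tri[, 1]] & on_plane[tri[, 2]] & on_plane[tri[, 3]]
    if (!any(flat)) next
    sel <- which(flat)
    p1 <- mesh$nodes[tri[sel, 1], , drop = FALSE] / 1000
    p2 <- mesh$nodes[tri[sel, 2], , drop = FALSE] / 1000
    p3 <- mesh$nodes[tri[sel, 3], , drop = FALSE] / 1000
    area <- 0.5 * sqrt(rowSums(cross3(p2 - p1, p3 - p1)^2))
    flux <- solution$sigma[sel] * solution$E[sel, axis] * area
    # element on the below side if its centroid is below the plane
    cent <- (mesh$nodes[mesh$elems[sel, 1], axis] +
               mesh$nodes[mesh$elems[sel, 2], axis] +
               mesh$nodes[mesh$elems[sel, 3], axis] +
               mesh$nodes[mesh$elems[sel, 4], axis]) / 4
    below <- cent < z0
    total["below"] <- total["below"] + sum(flux[below])
    total["above"] <- total["above"] + sum(flux[!below])
  }
  unname((total["below"] + total["above"]) / 2)
}

#' Export a tetrahedral mesh (with optional cell data) as legacy VTK
#' @param mesh a `tet_mesh`.
#' @param path output .vtk path.
#' @param cell_data optional named list of per-element numeric vectors.
#' @return the path, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(mesh$nodes))), con)
  write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  ne <- nrow(mesh$elems)
  writeLines(sprintf("CELLS %d %d", ne, ne * 5), con)
  write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
              col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(10L, ne)), con)
  if (!is.null(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(as.character(cell_data[[nm]]), con)
    }
  }
  invisible(path)
}
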