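# Synthetic "ventricle-in-ellipsoid-brain" phantom generator.
#
# The geometry is an idealized stand-in for a segmented brain: an ellipsoidal
# ventricular cavity with superellipsoid-like horn protrusions (the
# high-curvature features that concentrate wall loading), surrounded by a
# white-matter shell, a gray-matter shell and an ultrasoft subarachnoid shell,
# clamped at the outer surface. The cavity surface is a subdivided icosphere
# deformed by a radial shape function and extruded radially in conforming
# prism layers, giving a deterministic watertight tetrahedral mesh with a
# fine zone at the wall and a coarse zone in the parenchyma.

#' Phantom specification
#'
#' Parameters of the synthetic brain phantom. All lengths in mm.
#'
#' @param outer_radius Radius of the (spherical) outer surface.
#' @param gm_thickness Gray-matter shell thickness (measured along the radial
#'   extrusion direction).
#' @param sas_thickness Subarachnoid (CSF) shell thickness.
#' @param ventricle_semi_axes Semi-axes (a, b, c) of the ellipsoidal cavity.
#' @param n_horns Number of horn protrusions on the cavity.
#' @param horn_length Radial amplitude of each horn.
#' @param horn_tip_radius Lateral size of the horn tip; smaller values give
#'   sharper, higher-curvature tips.
#' @param target_edge_length_fine Target element edge length at the
#'   ventricular wall (fine zone).
#' @param target_edge_length_coarse Target edge length in the parenchyma.
#' @param wmh_placement One of `"at_horns"`, `"random_patches"`, `"none"`.
#' @param wmh_cap_thickness Thickness of the WMH cap placed on the wall.
#' @param seed Integer seed driving all randomness (horn jitter, random
#'   patch placement).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_radius = 30, gm_thickness = 4, sas_thickness = 3,
                         ventricle_semi_axes = c(9, 6, 5), n_horns = 2,
                         horn_length = 5, horn_tip_radius = 2,
                         target_edge_length_fine = 1.2,
                         target_edge_length_coarse = 2.4,
                         wmh_placement = c("at_horns", "random_patches", "none"),
                         wmh_cap_thickness = 3, seed = 1L) {
  wmh_placement <- match.arg(wmh_placement)
  spec <- structure(list(outer_radius = outer_radius, gm_thickness = gm_thickness,
                         sas_thickness = sas_thickness,
                         ventricle_semi_axes = ventricle_semi_axes,
                         n_horns = as.integer(n_horns), horn_length = horn_length,
                         horn_tip_radius = horn_tip_radius,
                         target_edge_length_fine = target_edge_length_fine,
                         target_edge_length_coarse = target_edge_length_coarse,
                         wmh_placement = wmh_placement,
                         wmh_cap_thickness = wmh_cap_thickness,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(ventricle_semi_axes <= 0)) stop("phantom_spec: ventricle_semi_axes must be positive")
    if (max(ventricle_semi_axes) + max(0, horn_length) + gm_thickness + sas_thickness >= outer_radius)
      stop("phantom_spec: ventricle_semi_axes + horn_length + gm_thickness + sas_thickness ",
           "must be smaller than outer_radius")
    if (n_horns > 0 && horn_tip_radius >= min(ventricle_semi_axes))
      stop("phantom_spec: horn_tip_radius must be smaller than the smallest semi-axis")
    if (target_edge_length_fine <= 0 || target_edge_length_coarse <= 0)
      stop("phantom_spec: edge lengths must be positive")
    if (target_edge_length_fine > target_edge_length_coarse)
      stop("phantom_spec: target_edge_length_fine must not exceed target_edge_length_coarse")
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("Phantom spec: outer R = %g mm, cavity semi-axes (%s) mm, ",
                     "%d horn(s) L = %g mm tip = %g mm,\n  GM %g mm, SAS %g mm, ",
                     "edges %g/%g mm (fine/coarse), WMH '%s' cap %g mm, seed %d\n"),
              x$outer_radius, paste(x$ventricle_semi_axes, collapse = ", "),
              x$n_horns, x$horn_length, x$horn_tip_radius, x$gm_thickness,
              x$sas_thickness, x$target_edge_length_fine, x$target_edge_length_coarse,
              x$wmh_placement, x$wmh_cap_thickness, x$seed))
  invisible(x)
}

# Unit icosahedron sphere, subdivided `level` times; outward-oriented faces.
icosphere <- function(level = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    mid_env <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid_env[[key]]
      if (!is.null(id)) return(id)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      mid_env[[key]] <- id
      id
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (q in seq_len(nrow(f))) {
      a <- f[q, 1]; b <- f[q, 2]; c <- f[q, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(4 * q - 3):(4 * q), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  # enforce outward orientation
  nn <- triangle_normals(v, f)$n2A
  cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  flip <- rowSums(nn * cen) < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  list(verts = v, faces = f)
}

# Cavity radius along unit directions: ellipsoid radial function plus
# Gaussian-profile horn bumps. `horns` is a list with dirs (k x 3), length,
# width (angular std dev).
cavity_radius <- function(dirs, semi_axes, horns) {
  r <- 1 / sqrt((dirs[, 1] / semi_axes[1])^2 + (dirs[, 2] / semi_axes[2])^2 +
                (dirs[, 3] / semi_axes[3])^2)
  if (!is.null(horns) && length(horns$length)) {
    for (k in seq_along(horns$length)) {
      ang <- acos(pmin(1, pmax(-1, dirs %*% horns$dirs[k, ])))
      r <- r + horns$length[k] * exp(-ang^2 / (2 * horns$width[k]^2))
    }
  }
  as.vector(r)
}

# Seeded horn geometry: directions roughly in the equatorial plane with small
# jittered azimuth/elevation and amplitude, so different seeds give genuinely
# different (but statistically equivalent) phantoms.
make_horns <- function(spec) {
  if (spec$n_horns == 0) return(NULL)
  with_seed(spec$seed, {
    az <- 2 * pi * (seq_len(spec$n_horns) - 1) / spec$n_horns +
      runif(spec$n_horns, -0.06, 0.06)
    el <- runif(spec$n_horns, -0.06, 0.06)
    len <- spec$horn_length * runif(spec$n_horns, 0.97, 1.03)
    dirs <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    # angular width from the requested tip radius: lateral size at the tip
    # is roughly width * (ellipsoid radius + horn length)
    rbase <- cavity_radius(dirs, spec$ventricle_semi_axes, NULL)
    width <- spec$horn_tip_radius / (rbase + len)
    list(dirs = dirs, length = len, width = width)
  })
}

# thickness ladder: fine at the wall, geometric growth capped at coarse
graded_thicknesses <- function(total, fine, coarse, growth = 1.6) {
  th <- c(); t <- fine
  while (sum(th) < total) {
    th <- c(th, t)
    t <- min(coarse, t * growth)
  }
  th * (total / sum(th))
}

#' Build the phantom mesh
#'
#' Generates the labeled tetrahedral mesh for a [phantom_spec()]: the
#' ventricular cavity is void (its elements are removed), the wall is tagged
#' `VENTRICULAR_WALL` (triangles oriented away from the cavity, the direction
#' a ventricular pressure pushes), the GM/SAS interface is tagged
#' `GM_CSF_INTERFACE` (oriented into gray matter) and the outer sphere
#' `OUTER_SURFACE`. Deterministic for a fixed spec (including seed). If
#' `wmh_placement` is not `"none"`, WMH labels are placed via
#' [place_wmh_labels()].
#'
#' @param spec A [phantom_spec()].
#' @param place_wmh Run WMH placement according to `spec$wmh_placement`
#'   (default TRUE).
#' @return A [labeled_mesh()] with a `phantom` attribute recording the spec
#'   and horn geometry.
#' @export
build_phantom_mesh <- function(spec, place_wmh = TRUE) {
  validate_phantom_spec(spec)
  horns <- make_horns(spec)
  # subdivision level from the fine target edge length at the wall
  probe <- icosphere(2)
  rbar <- mean(cavity_radius(probe$verts, spec$ventricle_semi_axes, horns))
  level <- 1
  while (1.0514 * rbar / 2^level > spec$target_edge_length_fine && level < 6) level <- level + 1
  ico <- icosphere(level)
  dirs <- ico$verts
  nv <- nrow(dirs)
  r0 <- cavity_radius(dirs, spec$ventricle_semi_axes, horns)
  r3 <- rep(spec$outer_radius, nv)
  r2 <- r3 - spec$sas_thickness
  r1 <- r2 - spec$gm_thickness
  tip_r <- if (is.null(horns)) max(r0)
           else max(cavity_radius(horns$dirs, spec$ventricle_semi_axes, horns))
  if (any(r1 <= r0 + 0.5 * spec$target_edge_length_fine) ||
      tip_r >= min(r1) - 0.5 * spec$target_edge_length_fine)
    stop("build_phantom_mesh: cavity (ventricle_semi_axes + horn_length) leaves no room ",
         "for the white-matter shell inside outer_radius - gm_thickness - sas_thickness")
  th_wm <- graded_thicknesses(mean(r1 - r0), spec$target_edge_length_fine,
                              spec$target_edge_length_coarse)
  n_wm <- length(th_wm)
  frac_wm <- cumsum(th_wm) / sum(th_wm)
  n_gm <- max(1L, round(spec$gm_thickness / spec$target_edge_length_coarse))
  n_sas <- max(1L, round(spec$sas_thickness / spec$target_edge_length_coarse))
  # radial knots per vertex: node layers from the wall outward
  layers <- list(r0)
  for (j in seq_len(n_wm)) layers[[length(layers) + 1L]] <- r0 + frac_wm[j] * (r1 - r0)
  for (j in seq_len(n_gm)) layers[[length(layers) + 1L]] <- r1 + (j / n_gm) * (r2 - r1)
  for (j in seq_len(n_sas)) layers[[length(layers) + 1L]] <- r2 + (j / n_sas) * (r3 - r2)
  L <- length(layers) - 1L          # number of element layers
  nodes <- do.call(rbind, lapply(layers, function(r) dirs * r))
  region_of_layer <- c(rep("WM", n_wm), rep("GM", n_gm), rep("SAS", n_sas))
  tets <- vector("list", L)
  for (l in seq_len(L)) {
    bot <- (l - 1L) * nv
    ids <- cbind(ico$faces + bot, ico$faces + bot + nv)
    tets[[l]] <- split_prisms(ids)
  }
  tets <- do.call(rbind, tets)
  region <- rep(region_of_layer, each = 3L * nrow(ico$faces))
  # orientation fix
  tmp_mesh <- labeled_mesh(nodes, tets, region, validate = FALSE)
  v <- tet_volumes(tmp_mesh)
  if (any(v == 0) || any(!is.finite(v)))
    stop("build_phantom_mesh: degenerate elements; geometry self-intersects ",
         "(reduce horn_length or increase horn_tip_radius)")
  flip <- v < 0
  if (any(flip)) {
    tmp <- tets[flip, 3]; tets[flip, 3] <- tets[flip, 4]; tets[flip, 4] <- tmp
  }
  wall <- ico$faces                              # layer 0, oriented outward (away from cavity)
  gmcsf <- ico$faces + nv * (n_wm + n_gm)
  gmcsf <- gmcsf[, c(1, 3, 2)]                   # into gray matter (toward cavity)
  outer_s <- ico$faces + nv * L                  # outward
  mesh <- labeled_mesh(nodes, tets, region,
                       surfaces = list(VENTRICULAR_WALL = wall,
                                       GM_CSF_INTERFACE = gmcsf,
                                       OUTER_SURFACE = outer_s))
  tip_nodes <- if (!is.null(horns))
    vapply(seq_len(spec$n_horns),
           function(k) which.max(dirs %*% horns$dirs[k, ]), integer(1))
  else integer(0)
  attr(mesh, "phantom") <- list(spec = spec, horns = horns, level = level,
                                horn_tip_nodes = tip_nodes)
  if (place_wmh && spec$wmh_placement != "none") mesh <- place_wmh_labels(mesh, spec)
  mesh
}

# Face-adjacency connected components of a tet subset; returns component id
# per element of `idx`.
tet_components <- function(mesh, idx) {
  if (!length(idx)) return(integer(0))
  sub <- mesh$tets[idx, , drop = FALSE]
  tf <- tet_faces(sub)
  keys <- face_key(tf$faces)
  dup <- split(tf$tet, keys)
  comp <- seq_along(idx)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (g in dup) if (length(g) == 2) {
    a <- find(g[1]); b <- find(g[2])
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  match(roots, unique(roots))
}

#' Place WMH labels on the phantom
#'
#' Relabels white-matter elements near the ventricular wall as `WMH`. In
#' `at_horns` mode the target wall patches are the top-decile mean-curvature
#' wall nodes (by construction the horn tips); in `random_patches` mode they
#' are seeded random wall patches. A WM element becomes WMH when its centroid
#' lies within `wmh_cap_thickness` of a selected wall node.
#'
#' @param mesh A [labeled_mesh()] from [build_phantom_mesh()].
#' @param spec The [phantom_spec()] (for placement mode, cap thickness, seed).
#' @return The mesh with updated region labels; the selected wall nodes are
#'   recorded in `attr(mesh, "phantom")$wmh_seed_nodes`.
#' @export
place_wmh_labels <- function(mesh, spec) {
  if (spec$wmh_placement == "none")
    stop("place_wmh_labels: wmh_placement is 'none'")
  if (spec$wmh_cap_thickness <= 0)
    stop("place_wmh_labels: wmh_cap_thickness must be positive (no candidate elements)")
  wall_nodes <- surface_nodes(mesh, "VENTRICULAR_WALL")
  if (spec$wmh_placement == "at_horns") {
    cf <- mean_curvature_field(mesh)
    K <- cf$K
    sel <- wall_nodes[!is.na(K) & K >= stats::quantile(K, 0.9, na.rm = TRUE)]
  } else {
    n_patch <- max(1L, spec$n_horns)
    sel <- with_seed(spec$seed + 1000L, {
      seeds <- sample(wall_nodes, n_patch)
      xs <- mesh$nodes[seeds, , drop = FALSE]
      keep <- logical(length(wall_nodes))
      for (q in seq_len(n_patch)) {
        d <- sqrt(rowSums((mesh$nodes[wall_nodes, , drop = FALSE] -
                           matrix(xs[q, ], length(wall_nodes), 3, byrow = TRUE))^2))
        keep <- keep | d <= 2 * spec$wmh_cap_thickness
      }
      wall_nodes[keep]
    })
  }
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
          mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  selx <- mesh$nodes[sel, , drop = FALSE]
  wm <- which(mesh$region == "WM")
  near <- logical(length(wm))
  cwm <- cen[wm, , drop = FALSE]
  for (q in seq_len(nrow(selx))) {
    d2 <- (cwm[, 1] - selx[q, 1])^2 + (cwm[, 2] - selx[q, 2])^2 + (cwm[, 3] - selx[q, 3])^2
    near <- near | d2 <= spec$wmh_cap_thickness^2
  }
  if (!any(near))
    stop("place_wmh_labels: no candidate elements within wmh_cap_thickness of the wall ",
         "(cap thickness smaller than the local element size)")
  mesh$region[wm[near]] <- "WMH"
  ph <- attr(mesh, "phantom")
  ph$wmh_seed_nodes <- sel
  attr(mesh, "phantom") <- ph
  mesh
}

#' Intensity volume container
#'
#' A scalar voxel volume with its grid geometry and the whole-brain and CSF
#' masks used by the WMH threshold segmentation.
#'
#' @param voxels 3D numeric array (arbitrary intensity units).
#' @param spacing Voxel spacing, length 3 (mm).
#' @param origin Position of the grid corner (mm); voxel (i,j,k) is centered
#'   at `origin + spacing * (c(i,j,k) - 0.5)`.
#' @param brain_mask,csf_mask Logical arrays of the same shape.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                             brain_mask = NULL, csf_mask = NULL) {
  stopifnot(length(dim(voxels)) == 3, all(spacing > 0))
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(voxels))
  if (is.null(csf_mask)) csf_mask <- array(FALSE, dim(voxels))
  stopifnot(identical(dim(brain_mask), dim(voxels)),
            identical(dim(csf_mask), dim(voxels)))
  if (any(csf_mask & !brain_mask)) stop("intensity_volume: csf_mask must be inside brain_mask")
  structure(list(voxels = voxels, spacing = rep(spacing, length.out = 3),
                 origin = origin, brain_mask = brain_mask, csf_mask = csf_mask),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Intensity volume: %d x %d x %d voxels, spacing (%s) mm, %d in brain mask\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = ", "),
              sum(x$brain_mask)))
  invisible(x)
}

# block-sum pooling of a logical/numeric subvoxel array to the voxel grid
block_pool <- function(arr_s, dims, s) {
  a6 <- array(arr_s, c(s, dims[1], s, dims[2], s, dims[3]))
  colSums(aperm(a6, c(1, 3, 5, 2, 4, 6)), dims = 3)
}

#' Synthesize a FLAIR-like intensity volume from a phantom mesh
#'
#' Region labels are rasterized at sub-voxel resolution (`subsample^3` samples
#' per voxel, point-in-tet at sample centers) and aggregated by majority to
#' voxel-level masks. Voxel intensities emulate a FLAIR acquisition whose
#' noise has been averaged over the sub-voxel blocks: brain voxels are
#' Gaussian with mean `background_mean` and standard deviation
#' `background_sd / subsample^(3/2)`, and voxels covered by WMH elements are
#' shifted up by `lesion_contrast * background_sd`. The CSF mask is the
#' ventricular cavity plus the subarachnoid shell. Deterministic per seed.
#'
#' @param mesh A [labeled_mesh()] (typically with WMH labels).
#' @param background_mean,background_sd Background intensity mean and
#'   sub-voxel noise level (arbitrary units).
#' @param lesion_contrast Lesion intensity shift in multiples of
#'   `background_sd`.
#' @param spacing Isotropic voxel spacing (mm).
#' @param seed Integer seed for the noise field.
#' @param subsample Sub-voxel rasterization factor per axis (default 3).
#' @return An [intensity_volume()]; the planted voxel-level lesion mask is
#'   attached as attribute `wmh_truth`.
#' @export
synthesize_flair_volume <- function(mesh, background_mean = 100, background_sd = 10,
                                    lesion_contrast = 4, spacing = 1.5, seed = 1L,
                                    subsample = 3L) {
  stopifnot(lesion_contrast > 0, spacing > 0, subsample >= 1)
  s <- as.integer(subsample)
  lo <- apply(mesh$nodes, 2, min) - 2 * spacing
  hi <- apply(mesh$nodes, 2, max) + 2 * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing))
  sp_s <- rep(spacing / s, 3)
  dims_s <- dims * s
  codes <- match(mesh$region, REGION_LEVELS)    # WM=1 GM=2 SAS=3 WMH=4
  lab_s <- .rasterize_labels(mesh$nodes, mesh$tets, codes, as.numeric(lo),
                             as.numeric(sp_s), dims_s)
  s3 <- s^3
  tissue_frac <- block_pool(lab_s > 0L, dims, s) / s3
  wmh_frac <- block_pool(lab_s == 4L, dims, s) / s3
  sas_frac <- block_pool(lab_s == 3L, dims, s) / s3
  tissue <- tissue_frac >= 0.5
  lesion <- wmh_frac >= 0.5
  sas_vox <- sas_frac >= 0.5
  # ventricular cavity: the connected non-tissue component containing the
  # voxel nearest the cavity centroid
  wall_c <- colMeans(mesh$nodes[surface_nodes(mesh, "VENTRICULAR_WALL"), , drop = FALSE])
  ci <- pmin(pmax(as.integer(round((wall_c - lo) / spacing + 0.5)), 1L), dims)
  comp <- label_components(!tissue, connectivity = 6)
  cav_id <- comp[ci[1], ci[2], ci[3]]
  cavity <- if (is.na(cav_id) || cav_id == 0) array(FALSE, dims) else comp == cav_id
  brain_mask <- tissue | cavity
  csf_mask <- cavity | sas_vox
  vox <- array(0, dims)
  n_in <- sum(brain_mask)
  noise <- with_seed(seed, rnorm(n_in, 0, background_sd / sqrt(s3)))
  vox[brain_mask] <- background_mean + noise
  vox[lesion] <- vox[lesion] + lesion_contrast * background_sd
  out <- intensity_volume(vox, spacing = rep(spacing, 3), origin = lo,
                          brain_mask = brain_mask, csf_mask = csf_mask)
  attr(out, "wmh_truth") <- lesion
  out
}
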