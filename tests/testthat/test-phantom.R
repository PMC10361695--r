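# Synthetic phantom generator: geometry/tag consistency, determinism,
# volume conservation, curvature ordering, WMH placement, FLAIR synthesis.

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(ventricle_semi_axes = c(20, 10, 10), horn_length = 10),
               "smaller than outer_radius")
  expect_error(phantom_spec(horn_tip_radius = 6), "smallest semi-axis")
  expect_error(phantom_spec(target_edge_length_fine = 3), "not exceed")
  expect_s3_class(phantom_spec(), "phantom_spec")
})

test_that("pure-ellipsoid phantom has consistent wall tags and watertight surfaces", {
  sp <- phantom_spec(n_horns = 0, horn_length = 0, wmh_placement = "none",
                     target_edge_length_fine = 2, target_edge_length_coarse = 3.5)
  m <- build_phantom_mesh(sp)
  expect_gt(length(surface_nodes(m, "VENTRICULAR_WALL")), 0)
  # every wall face borders exactly one tet, and that tet is white matter
  own <- surface_owner_tets(m, "VENTRICULAR_WALL")
  expect_true(all(m$region[own] == "WM"))
  tf <- ventriwall:::tet_faces(m$tets)
  counts <- table(ventriwall:::face_key(tf$faces))
  wall_keys <- ventriwall:::face_key(m$surfaces$VENTRICULAR_WALL)
  expect_true(all(counts[wall_keys] == 1L))
  for (tag in names(m$surfaces))
    expect_equal(nrow(surface_boundary_edges(m$surfaces[[tag]])), 0)
})

test_that("same seed gives byte-identical phantoms, different seeds differ", {
  sp <- coarse_spec(seed = 7)
  m1 <- build_phantom_mesh(sp)
  m2 <- build_phantom_mesh(sp)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$region, m2$region)
  m3 <- build_phantom_mesh(coarse_spec(seed = 8))
  expect_false(identical(m1$nodes, m3$nodes))
})

test_that("region volumes are consistent with the analytic shell volumes", {
  sp <- phantom_spec(n_horns = 0, horn_length = 0, wmh_placement = "none")
  m <- build_phantom_mesh(sp)
  v <- tet_volumes(m)
  r3 <- sp$outer_radius; r2 <- r3 - sp$sas_thickness; r1 <- r2 - sp$gm_thickness
  v_cav <- 4 / 3 * pi * prod(sp$ventricle_semi_axes)
  expect_equal(sum(v[m$region == "SAS"]), 4 / 3 * pi * (r3^3 - r2^3), tolerance = 0.05)
  expect_equal(sum(v[m$region == "GM"]), 4 / 3 * pi * (r2^3 - r1^3), tolerance = 0.05)
  expect_equal(sum(v[m$region == "WM"]), 4 / 3 * pi * r1^3 - v_cav, tolerance = 0.05)
  expect_equal(cavity_volume(m), v_cav, tolerance = 0.05)
})

test_that("sharper horn tips give higher maximum wall curvature", {
  k_of <- function(tip) {
    sp <- phantom_spec(horn_tip_radius = tip, wmh_placement = "none",
                       target_edge_length_fine = 1.5, target_edge_length_coarse = 3)
    max(mean_curvature_field(build_phantom_mesh(sp))$K, na.rm = TRUE)
  }
  expect_gt(k_of(2), k_of(4))
})

test_that("horn tips rank in the top decile of wall mean curvature", {
  m <- default_phantom()
  ph <- attr(m, "phantom")
  cf <- mean_curvature_field(m)
  thr <- quantile(cf$K, 0.9, na.rm = TRUE)
  k_tips <- cf$K[match(ph$horn_tip_nodes, cf$node)]
  expect_true(all(k_tips >= thr))
})

test_that("WMH placement modes behave as specified", {
  m <- default_phantom()
  sp <- attr(m, "phantom")$spec
  # at_horns: one WMH component per horn, each touching its horn tip
  idx <- which(m$region == "WMH")
  expect_gt(length(idx), 0)
  comp <- ventriwall:::tet_components(m, idx)
  expect_gte(max(comp), sp$n_horns)
  tips <- attr(m, "phantom")$horn_tip_nodes
  for (tip in tips) {
    touching <- unique(comp[apply(m$tets[idx, , drop = FALSE], 1,
                                  function(t4) tip %in% t4)])
    expect_gt(length(touching), 0)
  }
  # WMH is a subset of former WM elements touching the wall region
  base <- build_phantom_mesh(sp, place_wmh = FALSE)
  expect_true(all(base$region[idx] == "WM"))
  # degenerate cap thickness rejected
  sp0 <- sp; sp0$wmh_cap_thickness <- 0
  expect_error(place_wmh_labels(base, sp0), "positive")
  # random_patches deterministic per seed
  spr <- coarse_spec(seed = 3, wmh_placement = "random_patches")
  mr1 <- build_phantom_mesh(spr)
  mr2 <- build_phantom_mesh(spr)
  expect_identical(mr1$region, mr2$region)
  expect_gt(sum(mr1$region == "WMH"), 0)
})

test_that("meshing failure at extreme horn parameters raises a geometry error", {
  # passes the phantom_spec invariants but leaves no room for the WM shell over the
  # horn tip; the mesher must name the offending geometry
  sp <- phantom_spec(outer_radius = 31.5, ventricle_semi_axes = c(9, 6, 5),
                     horn_length = 14.4, gm_thickness = 5, sas_thickness = 3,
                     seed = 1)
  expect_error(build_phantom_mesh(sp), "no room|self-intersect")
})

test_that("FLAIR synthesis is seeded, Gaussian in the background, and rasterizes the lesion", {
  m <- coarse_phantom()
  v1 <- synthesize_flair_volume(m, spacing = 2, seed = 5)
  v2 <- synthesize_flair_volume(m, spacing = 2, seed = 5)
  expect_identical(v1$voxels, v2$voxels)
  v3 <- synthesize_flair_volume(m, spacing = 2, seed = 6)
  expect_false(identical(v1$voxels, v3$voxels))
  # masks nest and the cavity is inside the brain mask
  expect_true(all(v1$csf_mask <= v1$brain_mask))
  expect_gt(sum(v1$csf_mask), 0)
  truth <- attr(v1, "wmh_truth")
  expect_gt(sum(truth), 0)
  expect_true(all(v1$brain_mask[truth]))
  # background voxels (brain, non-lesion): mean ~ background_mean, sd reduced
  # by the 3^3 sub-voxel block averaging
  bg <- v1$voxels[v1$brain_mask & !truth]
  expect_equal(mean(bg), 100, tolerance = 0.5)
  expect_equal(sd(bg), 10 / sqrt(27), tolerance = 0.15)
  # lesion voxels shifted by lesion_contrast * background_sd
  expect_equal(mean(v1$voxels[truth]) - mean(bg), 40, tolerance = 2)
})

test_that("lesion voxels exceed the k = 2.5 threshold at contrast 4", {
  m <- default_phantom()
  v <- synthesize_flair_volume(m, lesion_contrast = 4, seed = 11)
  st <- estimate_stats(v, k = 2.5)
  mask <- threshold_mask(v, st)
  truth <- attr(v, "wmh_truth")
  expect_gte(sum(mask$mask & truth) / sum(truth), 0.99)
})
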