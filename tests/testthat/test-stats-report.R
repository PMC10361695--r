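# Wall node group classification, pooled t test, percent elevations, and the
# pipeline driver.

test_that("pooled t test matches hand computation and the reference routine", {
  tt <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -sqrt(3 / 2), tolerance = 1e-10)    # -1.224745
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-12)
  expect_equal(round(tt$p, 4), 0.2879)

  tt0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)

  set.seed(19)
  for (q in 1:100) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1), 0.3)
    tt <- two_sample_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_lt(abs(tt$t - unname(ref$statistic)), 1e-10)
    expect_equal(tt$df, unname(ref$parameter))
    expect_lt(abs(tt$p - ref$p.value), 1e-10)
    tw <- two_sample_t(a, b, welch = TRUE)
    refw <- t.test(a, b)
    expect_lt(abs(tw$t - unname(refw$statistic)), 1e-10)
    expect_lt(abs(tw$df - unname(refw$parameter)), 1e-8)
  }
  expect_error(two_sample_t(c(1, 1, 1), c(1, 1)), "variance")
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("wall node classification equals the breadth-first-search oracle", {
  m <- coarse_phantom()
  ws <- ventriwall:::wall_surface(m)
  marked <- ventriwall:::wall_face_wmh(m)
  expect_gt(sum(marked), 0)
  for (rings in c(1, 2)) {
    gr <- classify_wall_nodes(m, rings = rings)
    ring_faces <- bfs_rings_oracle(ws$tris, which(marked), rings)
    wmh_nodes <- sort(unique(as.vector(ws$tris_global[marked, , drop = FALSE])))
    adj_nodes <- sort(setdiff(unique(as.vector(ws$tris_global[ring_faces, , drop = FALSE])),
                              wmh_nodes))
    expect_identical(gr$wmh_nodes, wmh_nodes)
    expect_identical(gr$adjacent_nodes, adj_nodes)
  }
  gr0 <- classify_wall_nodes(m, rings = 0)
  expect_length(gr0$adjacent_nodes, 0)
})

test_that("group construction keeps groups disjoint and on the wall", {
  m <- coarse_phantom()
  gr <- classify_wall_nodes(m)
  expect_length(intersect(gr$wmh_nodes, gr$adjacent_nodes), 0)
  wall <- surface_nodes(m, "VENTRICULAR_WALL")
  expect_true(all(gr$wmh_nodes %in% wall))
  expect_true(all(gr$adjacent_nodes %in% wall))
})

fake_markers <- function(n, strain, thin, curv) {
  data.frame(node = seq_len(n), max_principal_strain = strain,
             thinning = thin, mean_curvature = curv)
}

test_that("percent elevations follow the group-mean ratio and schema", {
  mk <- fake_markers(6, strain = c(1, 2, 3, 2, 1, 3),
                     thin = c(0.014, 0.015, 0.016, 0.011, 0.012, 0.013),
                     curv = c(4, 5, 6, 1, 2, 3))
  gr <- structure(list(wmh_nodes = 1:3, adjacent_nodes = 4:6, rings = 2),
                  class = "node_groups")
  pe <- percent_elevations(mk, gr)
  expect_equal(nrow(pe), 3)
  expect_setequal(pe$marker, c("max_principal_strain", "thinning_ratio", "mean_curvature"))
  # equal means -> zero elevation, t = 0
  row <- pe[pe$marker == "max_principal_strain", ]
  expect_equal(row$pct_elevation, 0)
  expect_equal(row$t, 0)
  # 0.015 vs 0.012 -> 25% elevation
  row <- pe[pe$marker == "thinning_ratio", ]
  expect_equal(row$pct_elevation, 25, tolerance = 1e-10)
  row <- pe[pe$marker == "mean_curvature", ]
  expect_equal(row$df, 4)
  expect_equal(row$t, unname(t.test(4:6, 1:3, var.equal = TRUE)$statistic),
               tolerance = 1e-10)

  empty <- structure(list(wmh_nodes = integer(0), adjacent_nodes = 4:6, rings = 2),
                     class = "node_groups")
  expect_error(percent_elevations(mk, empty), "empty")
})

fast_config <- function(seed = 1) {
  cfg <- default_config(seed)
  cfg$phantom$target_edge_length_fine <- 2.5
  cfg$phantom$target_edge_length_coarse <- 4
  cfg$solver$n_load_increments <- 3
  cfg$segmentation$spacing <- 2
  cfg$stats$rings <- 2
  cfg
}

test_that("pipeline runs end to end and reports all three marker statistics", {
  rep <- run_pipeline(fast_config(seed = 2), verbose = FALSE)
  expect_true(rep$summary$converged)
  expect_s3_class(rep$stats, "group_stats")
  expect_equal(nrow(rep$stats), 3)
  expect_true(all(is.finite(rep$stats$p)))
  expect_gt(rep$summary$max_displacement_mm, 0)
  expect_gt(rep$segmentation$recall, 0.9)
})

test_that("pipeline is deterministic for a fixed seed", {
  r1 <- run_pipeline(fast_config(seed = 5), verbose = FALSE)
  r2 <- run_pipeline(fast_config(seed = 5), verbose = FALSE)
  j1 <- jsonlite::toJSON(r1$summary, auto_unbox = TRUE, digits = NA, force = TRUE)
  j2 <- jsonlite::toJSON(r2$summary, auto_unbox = TRUE, digits = NA, force = TRUE)
  expect_identical(j1, j2)
})

test_that("zero-pressure configuration skips the statistics gracefully", {
  cfg <- fast_config(seed = 3)
  cfg$loads$p_lv_kpa <- 0
  cfg$loads$p_sas_kpa <- 0
  cfg$segmentation$enabled <- FALSE
  rep <- run_pipeline(cfg, verbose = FALSE)
  expect_null(rep$stats)
  expect_true(is.character(rep$summary$group_stats))
  expect_equal(rep$summary$max_displacement_mm, 0)
})

test_that("pipeline writes its output bundle", {
  out <- file.path(tempdir(), "vw_test_out")
  on.exit(unlink(out, recursive = TRUE))
  rep <- run_pipeline(fast_config(seed = 4), out_dir = out, verbose = FALSE)
  expect_true(file.exists(file.path(out, "phantom.vtu")))
  expect_true(file.exists(file.path(out, "solution.vtu")))
  expect_true(file.exists(file.path(out, "wall_markers.csv")))
  expect_true(file.exists(file.path(out, "group_stats.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "log.txt")))
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(js$seed, 4)
  mk <- read.csv(file.path(out, "wall_markers.csv"))
  expect_equal(nrow(mk), rep$summary$n_wall_nodes)
})
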