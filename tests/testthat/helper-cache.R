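# Shared fixture cache: expensive meshes/solves are built once per test run
# and reused across test files (helpers are sourced once by testthat).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# small default-spec phantom used by several files (full default resolution)
default_phantom <- function() cached("default_phantom", build_phantom_mesh(phantom_spec()))

# coarse, fast phantom for solver-heavy unit tests: same construction, fewer
# elements
coarse_spec <- function(seed = 1, ...) {
  phantom_spec(target_edge_length_fine = 2.5, target_edge_length_coarse = 4,
               seed = seed, ...)
}
coarse_phantom <- function() cached("coarse_phantom", build_phantom_mesh(coarse_spec()))

# spherical shell reused by the harmonic-field checks
shell_10_20 <- function() {
  cached("shell_10_20", spherical_shell_mesh(10, 20, n_layers = 8, level = 3))
}

# sphere curvature fields at several refinement levels (radius 10)
sphere_curvature <- function(level) {
  cached(paste0("sphere_curv_", level), {
    m <- spherical_shell_mesh(10, 13, n_layers = 1, level = level)
    mean_curvature_field(m)
  })
}

# randomized slab fixtures comparing wmh_thickness against the brute-force
# ray-marching oracle; interior nodes are jittered so rays do not run along
# mesh edges (where the traversal order is genuinely ambiguous). The linear
# Laplace field stays exact because boundary faces are untouched.
slab_thickness_cases <- function(n_cases = 20) {
  cached("slab_thickness_cases", {
    set.seed(506)
    lz <- 10
    out <- vector("list", n_cases)
    for (rep in seq_len(n_cases)) {
      nz <- sample(4:6, 1)
      m <- box_mesh(3, 3, nz, 6, 6, lz, region = "WM")
      interior <- which(m$nodes[, 1] > 0 & m$nodes[, 1] < 6 &
                        m$nodes[, 2] > 0 & m$nodes[, 2] < 6 & m$nodes[, 3] < lz)
      m$nodes[interior, 1:2] <- m$nodes[interior, 1:2] +
        matrix(runif(2 * length(interior), -0.2, 0.2), ncol = 2)
      m$surfaces$VENTRICULAR_WALL <- m$surfaces$ZMIN
      # cap depth snapped to a layer boundary so the WMH/WM interface is a
      # clean plane: the furthest intersected WMH element is then unambiguous
      # (a ragged element-wise boundary makes grazing intersections genuinely
      # order-ambiguous between any two traversal algorithms)
      hz <- lz / nz
      d <- hz * sample(seq_len(nz - 2), 1)
      cen_z <- (m$nodes[m$tets[, 1], 3] + m$nodes[m$tets[, 2], 3] +
                m$nodes[m$tets[, 3], 3] + m$nodes[m$tets[, 4], 3]) / 4
      m$region[cen_z < d] <- "WMH"
      f <- solve_laplace(m, bc_values = list(VENTRICULAR_WALL = 1, ZMAX = 0))
      fr <- compute_wall_frames(f, m)
      th <- wmh_thickness(m, fr)
      wn <- th$node
      inner <- wn[m$nodes[wn, 1] > 1 & m$nodes[wn, 1] < 5 &
                  m$nodes[wn, 2] > 1 & m$nodes[wn, 2] < 5]
      v <- sample(inner, 1)
      orc <- thickness_oracle(m, m$nodes[v, ], c(0, 0, 1), step = hz / 60,
                              max_dist = lz + 1)
      out[[rep]] <- data.frame(depth = d, got = th$thickness[th$node == v],
                               oracle = orc, diag = sqrt(2.4^2 + 2.4^2 + hz^2))
    }
    do.call(rbind, out)
  })
}

# five seeded end-to-end runs at the default study conditions (markers +
# statistics; FLAIR synthesis disabled here, exercised separately)
pipeline_runs <- function(seeds = 1:5) {
  cached("pipeline_runs", lapply(seeds, function(s) {
    cfg <- default_config(seed = s)
    cfg$segmentation$enabled <- FALSE
    run_pipeline(cfg, verbose = FALSE)
  }))
}

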