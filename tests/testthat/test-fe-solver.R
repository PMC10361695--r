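# Nonlinear FE solver: assembly consistency, equilibrium states, patch test,
# pressure loading, shrinkage (atrophy) variant, sensitivity sweep.

single_tet_mesh <- function() {
  labeled_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               matrix(1:4, 1), "GM")
}

test_that("reference state with zero pressure is in equilibrium", {
  m <- box_mesh(2, 2, 2)
  bcs <- boundary_conditions(fixed_nodes = surface_nodes(m, "XMIN"))
  asm <- assemble_system(m, default_tissue_table(), numeric(3 * nrow(m$nodes)), bcs)
  expect_equal(max(abs(asm$residual)), 0)
  sol <- solve_quasistatic(m, default_tissue_table(), bcs,
                           solver_settings(n_load_increments = 2))
  expect_true(sol$converged)
  expect_equal(max(abs(sol$nodal_displacements)), 0)
})

test_that("assembled tangent matches finite differences of the residual", {
  m <- single_tet_mesh()
  tab <- default_tissue_table()
  bcs <- boundary_conditions()               # no constraints: full system
  set.seed(2)
  u <- rnorm(12, 0, 0.02)
  asm <- assemble_system(m, tab, u, bcs)
  K <- as.matrix(asm$tangent)
  h <- 1e-7
  Kfd <- matrix(0, 12, 12)
  for (j in 1:12) {
    up <- u; up[j] <- up[j] + h
    um <- u; um[j] <- um[j] - h
    rp <- assemble_system(m, tab, up, bcs, want_tangent = FALSE)$residual
    rm <- assemble_system(m, tab, um, bcs, want_tangent = FALSE)$residual
    Kfd[, j] <- (rp - rm) / (2 * h)
  }
  expect_lt(max(abs(K - Kfd)) / max(abs(K)), 1e-5)
})

test_that("follower pressure load stiffness matches finite differences", {
  m <- box_mesh(1, 1, 1)
  tab <- default_tissue_table()
  bcs <- boundary_conditions(pressure_loads = list(ZMAX = 0.2))
  set.seed(4)
  u <- rnorm(3 * nrow(m$nodes), 0, 0.03)
  asm <- assemble_system(m, tab, u, bcs, pressure_mode = "follower")
  K <- as.matrix(asm$tangent)
  h <- 1e-7
  n <- length(u)
  Kfd <- matrix(0, n, n)
  for (j in seq_len(n)) {
    up <- u; up[j] <- up[j] + h
    um <- u; um[j] <- um[j] - h
    rp <- assemble_system(m, tab, up, bcs, pressure_mode = "follower",
                          want_tangent = FALSE)$residual
    rm <- assemble_system(m, tab, um, bcs, pressure_mode = "follower",
                          want_tangent = FALSE)$residual
    Kfd[, j] <- (rp - rm) / (2 * h)
  }
  expect_lt(max(abs(K - Kfd)) / max(abs(K)), 1e-5)
  # dead mode: external force independent of u
  a1 <- assemble_system(m, tab, u, bcs, pressure_mode = "dead", want_tangent = FALSE)
  a2 <- assemble_system(m, tab, numeric(n), bcs, pressure_mode = "dead",
                        want_tangent = FALSE)
  expect_equal(a1$fext, a2$fext)
})

test_that("unloaded tangent is symmetric positive definite after BC elimination", {
  m <- box_mesh(1, 1, 1)
  bcs <- boundary_conditions(fixed_nodes = surface_nodes(m, "XMIN"))
  asm <- assemble_system(m, default_tissue_table(), numeric(3 * nrow(m$nodes)), bcs)
  K <- as.matrix(asm$tangent)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("uniaxial-stress patch test is exact on an unstructured block", {
  # rollers on three orthogonal faces, follower pressure on the +x face:
  # the homogeneous uniaxial-stress state is reproduced element-wise
  m <- box_mesh(2, 2, 2, region = "GM")
  p <- 0.05
  bcs <- boundary_conditions(
    pressure_loads = list(XMAX = p),
    constraints = list(list(nodes = surface_nodes(m, "XMIN"), dims = 1),
                       list(nodes = surface_nodes(m, "YMIN"), dims = 2),
                       list(nodes = surface_nodes(m, "ZMIN"), dims = 3)))
  sol <- solve_quasistatic(m, default_tissue_table(), bcs,
                           solver_settings(n_load_increments = 2,
                                           newton_rel_tol = 1e-13))
  expect_true(sol$converged)
  Fs <- matrix(sol$element_F, 9)
  expect_lt(max(apply(Fs, 1, sd)), 1e-10)                 # homogeneous
  F1 <- sol$element_F[, , 1]
  expect_lt(max(abs(F1 - diag(diag(F1)))), 1e-10)         # diagonal
  sig <- cauchy_stress(decompose_deformation(F1), default_tissue_table()$GM)
  expect_equal(sig[1, 1], -p, tolerance = 1e-9)
  expect_lt(max(abs(sig[2, 2]), abs(sig[3, 3])), 1e-9)
  # matches the semi-analytic uniaxial oracle
  orc <- uniaxial_state(-p, 0.34, 3.3)
  expect_equal(F1[1, 1], orc$lambda_ax, tolerance = 1e-8)
  expect_equal(F1[2, 2], orc$lambda_lat, tolerance = 1e-8)
})

test_that("displacements are linear in the load in the small-pressure limit", {
  m <- spherical_shell_mesh(8, 14, n_layers = 3, level = 2)
  tab <- default_tissue_table()
  solve_p <- function(p) {
    bcs <- boundary_conditions(fixed_nodes = surface_nodes(m, "OUTER_SURFACE"),
                               pressure_loads = list(VENTRICULAR_WALL = p))
    solve_quasistatic(m, tab, bcs, solver_settings(n_load_increments = 1))
  }
  u1 <- solve_p(0.0015)$nodal_displacements     # 1.5 Pa
  u2 <- solve_p(0.0030)$nodal_displacements
  ratio <- max(abs(u2)) / max(abs(u1))
  expect_equal(ratio, 2, tolerance = 0.01)
})

test_that("solver reports non-convergence gracefully", {
  m <- single_tet_mesh()
  m$surfaces$TOP <- matrix(c(2, 3, 4), 1)
  bcs <- boundary_conditions(fixed_nodes = 1L, pressure_loads = list(TOP = 50))
  sol <- tryCatch(solve_quasistatic(m, default_tissue_table(), bcs,
                                    solver_settings(n_load_increments = 1,
                                                    max_newton_iters = 3)),
                  error = function(e) e)
  ok <- inherits(sol, "error") ||
    (!sol$converged && sol$increments_completed < 1)
  expect_true(ok)
})

test_that("isotropic shrinkage matches the target cavity volume gain", {
  m <- spherical_shell_mesh(8, 14, n_layers = 3, level = 2)
  tab <- default_tissue_table()
  sol0 <- apply_isotropic_shrinkage(m, tab, target_cavity_volume_gain = 0,
                                    settings = solver_settings(n_load_increments = 2))
  expect_equal(attr(sol0, "g"), 1)
  expect_equal(max(abs(sol0$nodal_displacements)), 0)

  sol <- apply_isotropic_shrinkage(m, tab, target_cavity_volume_gain = 0.10,
                                   settings = solver_settings(n_load_increments = 3))
  expect_true(sol$converged)
  expect_lt(attr(sol, "g"), 1)
  expect_equal(attr(sol, "cavity_gain"), 0.10, tolerance = 0.005)

  # cavity gain strictly increases as g decreases
  gain_of <- function(g) {
    gv <- rep(g, nrow(m$tets))
    s <- ventriwall:::newton_ramp(m, tab,
      boundary_conditions(fixed_nodes = surface_nodes(m, "OUTER_SURFACE")),
      solver_settings(n_load_increments = 3), growth_target = gv)
    cavity_volume(m, s$nodal_displacements) / cavity_volume(m) - 1
  }
  gains <- vapply(c(0.99, 0.97, 0.95), gain_of, numeric(1))
  expect_true(all(diff(gains) > 0))
})

test_that("sensitivity sweep is consistent with single solves and physically ordered", {
  m <- coarse_phantom()
  tab <- default_tissue_table()
  bcs <- default_boundary_conditions(m)
  st <- solver_settings(n_load_increments = 4)
  sw <- run_sensitivity_sweep(m, tab, bcs,
                              sweep = list(p_lv = c(0.1, 0.3, 0.9),
                                           wm_gm_ratio = c(0.25, 2)),
                              settings = st)
  expect_true(all(sw$converged))
  # baseline row identical to a direct solve
  base <- solve_quasistatic(m, tab, bcs, st)
  ws <- ventriwall:::wall_summary(m, base)
  row <- sw[sw$parameter == "p_lv" & sw$value == 0.3, ]
  expect_identical(row$max_principal_strain, unname(ws["max_principal_strain"]))
  expect_identical(row$max_wall_displacement, unname(ws["max_wall_displacement"]))
  # wall strain magnitude increases monotonically with ventricular pressure
  pl <- sw[sw$parameter == "p_lv", ]
  expect_true(all(diff(pl$max_abs_principal_strain[order(pl$value)]) > 0))
  # softening white matter (ratio 2 -> 1/4) increases max wall displacement
  wr <- sw[sw$parameter == "wm_gm_ratio", ]
  expect_gt(wr$max_wall_displacement[wr$value == 0.25],
            wr$max_wall_displacement[wr$value == 2])
})
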