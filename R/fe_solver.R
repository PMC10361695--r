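# Quasi-static nonlinear finite-element solver: displacement-based linear
# tetrahedra with single-point quadrature, total-Lagrangian formulation,
# surface pressure loads (follower by default), fixed outer boundary, Newton
# iterations with proportional load ramping. Sparse linear algebra via the
# Matrix package (direct LU, deterministic).

#' Boundary conditions
#'
#' @param fixed_nodes Integer vector of fully fixed nodes (all three dofs).
#' @param pressure_loads Named numeric vector/list: surface tag -> pressure
#'   magnitude in kPa. Each load acts along the stored triangle normals of the
#'   tagged surface (which point into the loaded tissue).
#' @param constraints Optional list of single-dof constraints, each a list
#'   with `nodes` (integer vector) and `dims` (subset of 1:3); used for roller
#'   supports in verification problems.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(fixed_nodes = integer(), pressure_loads = list(),
                                constraints = list()) {
  pressure_loads <- as.list(pressure_loads)
  if (any(unlist(pressure_loads) < 0)) stop("boundary_conditions: pressure magnitudes must be >= 0")
  structure(list(fixed_nodes = as.integer(fixed_nodes),
                 pressure_loads = pressure_loads, constraints = constraints),
            class = "boundary_conditions")
}

#' Default hemodynamic loading
#'
#' Peak hemodynamic pressurization: 0.300 kPa (300 Pa) on the ventricular wall
#' acting against white matter, 0.290 kPa (290 Pa) on the gray-matter/CSF
#' interface acting against gray matter, zero displacement on all outer
#' surface nodes.
#'
#' @param mesh A [labeled_mesh()] with the three phantom surface tags.
#' @param p_lv Ventricular pressure in kPa (default 0.300).
#' @param p_sas Subarachnoid pressure in kPa (default 0.290).
#' @return A [boundary_conditions()] object.
#' @export
default_boundary_conditions <- function(mesh, p_lv = 0.300, p_sas = 0.290) {
  boundary_conditions(fixed_nodes = surface_nodes(mesh, "OUTER_SURFACE"),
                      pressure_loads = list(VENTRICULAR_WALL = p_lv,
                                            GM_CSF_INTERFACE = p_sas))
}

#' Solver settings
#'
#' @param n_load_increments Number of proportional load increments.
#' @param newton_rel_tol Relative residual tolerance (vs external force norm).
#' @param newton_abs_tol Absolute residual tolerance (native kPa mm^2 force
#'   units).
#' @param max_newton_iters Maximum Newton iterations per increment.
#' @param pressure_mode `"follower"` (pressure stays normal to the deforming
#'   surface, with consistent load stiffness) or `"dead"` (reference normals).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(n_load_increments = 10, newton_rel_tol = 1e-8,
                            newton_abs_tol = 1e-10, max_newton_iters = 25,
                            pressure_mode = c("follower", "dead")) {
  pressure_mode <- match.arg(pressure_mode)
  stopifnot(n_load_increments >= 1, newton_rel_tol > 0, newton_abs_tol > 0)
  structure(list(n_load_increments = as.integer(n_load_increments),
                 newton_rel_tol = newton_rel_tol, newton_abs_tol = newton_abs_tol,
                 max_newton_iters = as.integer(max_newton_iters),
                 pressure_mode = pressure_mode),
            class = "solver_settings")
}

# per-element material parameters from the tissue table
element_params <- function(mesh, table) {
  mu <- vapply(mesh$region, function(r) table[[r]]$mu, numeric(1), USE.NAMES = FALSE)
  kappa <- vapply(mesh$region, function(r) table[[r]]$kappa, numeric(1), USE.NAMES = FALSE)
  list(mu = mu, kappa = kappa)
}

# dof bookkeeping: fixed dof indices (1-based over 3N, node-major x,y,z)
fixed_dof_indices <- function(mesh, bcs) {
  fd <- as.vector(t(outer(3 * (bcs$fixed_nodes - 1L), 1:3, "+")))
  for (ct in bcs$constraints)
    fd <- c(fd, as.vector(outer(3 * (as.integer(ct$nodes) - 1L), as.integer(ct$dims), "+")))
  sort(unique(fd))
}

#' Assemble residual and tangent of the equilibrium system
#'
#' Residual = internal forces - external pressure forces at the current
#' displacement; tangent = material + geometric stiffness, plus the load
#' stiffness of follower pressures. Rows/columns of fixed dofs are eliminated.
#'
#' @param mesh A [labeled_mesh()].
#' @param table A [default_tissue_table()] (or compatible) tissue table.
#' @param u Nodal displacement vector, length `3 * nrow(mesh$nodes)`
#'   (node-major x,y,z), or an N x 3 matrix.
#' @param bcs A [boundary_conditions()] object.
#' @param load_factor Scale applied to all pressure magnitudes (ramping).
#' @param pressure_mode `"follower"` or `"dead"`.
#' @param growth Optional per-element isotropic eigenstrain factors g
#'   (default 1; g < 1 shrinks the element's stress-free configuration).
#' @param want_tangent Assemble the sparse tangent (default TRUE).
#' @return A list with `residual` (free dofs), `tangent` (sparse, free dofs,
#'   `NULL` if not requested), `free` (free dof indices), `fint`, `fext`
#'   (full vectors), `element_F` (3x3xM array), `energy`, `bad_element`.
#' @export
assemble_system <- function(mesh, table, u, bcs, load_factor = 1,
                            pressure_mode = "follower", growth = NULL,
                            want_tangent = TRUE) {
  N <- nrow(mesh$nodes); M <- nrow(mesh$tets)
  if (is.matrix(u)) u <- as.vector(t(u))
  stopifnot(length(u) == 3 * N)
  ep <- element_params(mesh, table)
  if (is.null(growth)) growth <- rep(1, M)
  ai <- .asm_internal(mesh$nodes, mesh$tets, u, ep$mu, ep$kappa, growth, want_tangent)
  fext <- numeric(3 * N)
  pt_i <- list(); pt_j <- list(); pt_x <- list()
  for (tag in names(bcs$pressure_loads)) {
    p <- bcs$pressure_loads[[tag]] * load_factor
    if (p == 0) next
    tris <- mesh$surfaces[[tag]]
    if (is.null(tris)) stop("assemble_system: no surface tagged '", tag, "'")
    ap <- .asm_pressure(mesh$nodes, tris, u, p, pressure_mode == "follower", want_tangent)
    fext <- fext + ap$fext
    if (!is.null(ap$ti)) {
      pt_i[[tag]] <- ap$ti; pt_j[[tag]] <- ap$tj; pt_x[[tag]] <- ap$tx
    }
  }
  fd <- fixed_dof_indices(mesh, bcs)
  free <- setdiff(seq_len(3 * N), fd)
  res <- (ai$fint - fext)[free]
  K <- NULL
  if (want_tangent) {
    px <- if (length(pt_x)) -unlist(pt_x, use.names = FALSE) else numeric(0)
    ti <- c(ai$ti, unlist(pt_i, use.names = FALSE))
    tj <- c(ai$tj, unlist(pt_j, use.names = FALSE))
    tx <- c(ai$tx, px)
    if (is.null(ti)) { ti <- integer(0); tj <- integer(0); tx <- numeric(0) }
    Kfull <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(3 * N, 3 * N))
    K <- Kfull[free, free, drop = FALSE]
  }
  list(residual = res, tangent = K, free = free, fint = ai$fint, fext = fext,
       element_F = array(ai$F, c(3, 3, M)), energy = ai$energy,
       bad_element = ai$bad_element)
}

new_solution_field <- function(mesh, u, asm, converged, history, increments) {
  structure(list(nodal_displacements = matrix(u, ncol = 3, byrow = TRUE),
                 element_F = asm$element_F, converged = converged,
                 residual_history = history,
                 increments_completed = increments),
            class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  um <- sqrt(rowSums(x$nodal_displacements^2))
  cat(sprintf("Solution field: %d nodes, converged = %s, max |u| = %.4g mm\n",
              nrow(x$nodal_displacements), x$converged, max(um)))
  invisible(x)
}

# Sparse solve of the Newton system. The tangent of the pressurized-cavity
# problem is symmetric (enclosed follower pressure is a conservative load),
# so a supernodal Cholesky factorization is tried first, with a sparse LU
# fallback for indefinite tangents far from equilibrium.
newton_solve <- function(K, r) {
  du <- tryCatch({
    Ks <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
    ch <- Matrix::Cholesky(Ks, LDL = FALSE, super = TRUE)
    as.numeric(Matrix::solve(ch, r))
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(du) || anyNA(du)) du <- as.numeric(Matrix::solve(K, r))
  -du
}

# core Newton loop with proportional ramping of pressures and growth; a step
# that inverts an element is halved (up to 12 times) before re-assembly
newton_ramp <- function(mesh, table, bcs, settings, growth_target = NULL) {
  N <- nrow(mesh$nodes)
  u <- numeric(3 * N)
  history <- list()
  inc_done <- 0
  asm <- NULL
  u_conv <- list()                      # converged states per increment
  free <- setdiff(seq_len(3 * N), fixed_dof_indices(mesh, bcs))
  for (inc in seq_len(settings$n_load_increments)) {
    lam <- inc / settings$n_load_increments
    g <- if (is.null(growth_target)) NULL else 1 + lam * (growth_target - 1)
    rnorms <- numeric(0)
    ok <- FALSE
    u_prev <- NULL; du <- NULL; step <- 1; halvings <- 0; is_pred <- FALSE
    # first-order predictor: equal load steps, so extrapolating the previous
    # increment's displacement change is an excellent Newton starting guess
    if (inc >= 2) {
      pred <- if (inc == 2) u_conv[[1]] else u_conv[[inc - 1]] - u_conv[[inc - 2]]
      u_prev <- u; du <- pred[free]; step <- 1; halvings <- 0; is_pred <- TRUE
      u[free] <- u[free] + du
    }
    for (it in seq_len(settings$max_newton_iters)) {
      asm <- assemble_system(mesh, table, u, bcs, load_factor = lam,
                             pressure_mode = settings$pressure_mode, growth = g)
      if (asm$bad_element > 0) {
        if (is_pred) {
          # discard a predictor that left the admissible set
          u <- u_prev; u_prev <- NULL; du <- NULL; is_pred <- FALSE
          next
        }
        if (is.null(du) || halvings >= 12)
          stop(sprintf("solver: inverted element %d at increment %d", asm$bad_element, inc))
        step <- step / 2; halvings <- halvings + 1
        u <- u_prev
        u[asm$free] <- u[asm$free] + step * du
        next
      }
      is_pred <- FALSE
      rn <- sqrt(sum(asm$residual^2))
      rnorms <- c(rnorms, rn)
      fref <- sqrt(sum((asm$fext[asm$free])^2))
      if (!is.null(growth_target)) fref <- max(fref, sqrt(sum(asm$fint[asm$free]^2)))
      if (rn <= settings$newton_abs_tol || (fref > 0 && rn <= settings$newton_rel_tol * fref)) {
        ok <- TRUE; break
      }
      du <- newton_solve(asm$tangent, asm$residual)
      u_prev <- u
      step <- 1; halvings <- 0
      u[asm$free] <- u[asm$free] + du
    }
    history[[inc]] <- rnorms
    if (!ok) {
      return(new_solution_field(mesh, u, asm, converged = FALSE, history,
                                increments = inc_done))
    }
    inc_done <- inc
    u_conv[[inc]] <- u
  }
  new_solution_field(mesh, u, asm, converged = TRUE, history, inc_done)
}

#' Quasi-static solve to peak pressure
#'
#' Ramps all surface pressures proportionally over the load increments and
#' solves each increment by Newton iteration until the residual tolerance is
#' met. On success the returned field has `converged = TRUE` and per-element
#' deformation gradients from the final displacement state; on failure the
#' last converged increment is recorded and `converged = FALSE`.
#'
#' @inheritParams assemble_system
#' @param settings A [solver_settings()] object.
#' @return An object of class `solution_field` with `nodal_displacements`
#'   (N x 3, mm), `element_F` (3x3xM), `converged`, `residual_history`,
#'   `increments_completed`.
#' @export
solve_quasistatic <- function(mesh, table, bcs, settings = solver_settings()) {
  newton_ramp(mesh, table, bcs, settings)
}

#' Simulate cerebral atrophy by uniform tissue shrinkage
#'
#' Applies a multiplicative isotropic eigenstrain F = F_elastic (g I), g < 1,
#' to the white- and gray-matter elements (WMH elements shrink with white
#' matter) and finds, by bisection on g, the equilibrium at which the
#' ventricular cavity volume has increased by `target_cavity_volume_gain`
#' (e.g. 0.20 for a 20 percent gain).
#'
#' @inheritParams solve_quasistatic
#' @param shrink_regions Region labels to shrink (default WM, GM; "WM"
#'   includes WMH elements).
#' @param target_cavity_volume_gain Fractional cavity volume increase.
#' @param g_bracket Search bracket for the shrinkage factor g.
#' @param tol Tolerance on the achieved volume gain (default 0.002).
#' @return A `solution_field` with attributes `g` (matched shrinkage factor)
#'   and `cavity_gain` (achieved fractional gain).
#' @export
apply_isotropic_shrinkage <- function(mesh, table, shrink_regions = c("WM", "GM"),
                                      target_cavity_volume_gain,
                                      settings = solver_settings(n_load_increments = 4),
                                      g_bracket = c(0.85, 1), tol = 0.002) {
  stopifnot(target_cavity_volume_gain >= 0)
  regions <- shrink_regions
  if ("WM" %in% regions) regions <- union(regions, "WMH")
  in_shrink <- mesh$region %in% regions
  V0 <- cavity_volume(mesh)
  no_load <- boundary_conditions(fixed_nodes = surface_nodes(mesh, "OUTER_SURFACE"))
  solve_g <- function(g) {
    gv <- rep(1, nrow(mesh$tets)); gv[in_shrink] <- g
    newton_ramp(mesh, table, no_load, settings, growth_target = gv)
  }
  gain_of <- function(g) {
    sol <- solve_g(g)
    if (!sol$converged) stop(sprintf("apply_isotropic_shrinkage: no convergence at g = %.4f", g))
    cavity_volume(mesh, sol$nodal_displacements) / V0 - 1
  }
  if (target_cavity_volume_gain == 0) {
    sol <- solve_g(1)
    attr(sol, "g") <- 1; attr(sol, "cavity_gain") <- 0
    return(sol)
  }
  f_hi <- gain_of(g_bracket[2])            # ~0 at g = 1
  f_lo <- gain_of(g_bracket[1])
  if (f_lo < target_cavity_volume_gain)
    stop(sprintf(paste0("apply_isotropic_shrinkage: bracket [%g, %g] reaches gain %.3f < ",
                        "target %.3f; widen g_bracket downward"),
         g_bracket[1], g_bracket[2], f_lo, target_cavity_volume_gain))
  root <- stats::uniroot(function(g) gain_of(g) - target_cavity_volume_gain,
                         interval = g_bracket, f.lower = f_lo - target_cavity_volume_gain,
                         f.upper = f_hi - target_cavity_volume_gain, tol = 1e-4)
  g <- root$root
  sol <- solve_g(g)
  gain <- cavity_volume(mesh, sol$nodal_displacements) / V0 - 1
  if (abs(gain - target_cavity_volume_gain) > max(tol, 0.005))
    warning(sprintf("apply_isotropic_shrinkage: achieved gain %.4f vs target %.4f", gain,
                    target_cavity_volume_gain))
  attr(sol, "g") <- g
  attr(sol, "cavity_gain") <- gain
  sol
}

# wall-level summary measures used by the sensitivity sweep
wall_summary <- function(mesh, sol) {
  wall_tets <- unique(surface_owner_tets(mesh, "VENTRICULAR_WALL"))
  mps <- vapply(wall_tets, function(e) max_principal_strain(sol$element_F[, , e]), numeric(1))
  wn <- surface_nodes(mesh, "VENTRICULAR_WALL")
  um <- sqrt(rowSums(sol$nodal_displacements[wn, , drop = FALSE]^2))
  c(max_principal_strain = max(mps),
    max_abs_principal_strain = max(abs(mps)),
    max_wall_displacement = max(um))
}

#' Sensitivity sweep over pressures and stiffness ratio
#'
#' Runs one quasi-static solve per setting: ventricular pressures `p_lv`
#' (kPa, keeping the baseline SAS/LV pressure ratio), SAS/LV pressure ratios
#' at the baseline ventricular pressure, and white-to-gray stiffness ratios at
#' baseline pressures. Reports maximum principal strain over wall elements and
#' maximum wall displacement for each setting.
#'
#' @inheritParams solve_quasistatic
#' @param base_bcs Baseline [boundary_conditions()] (must contain
#'   `VENTRICULAR_WALL` and `GM_CSF_INTERFACE` pressure loads).
#' @param sweep List with any of `p_lv` (numeric vector, kPa), `p_ratio`
#'   (p_SAS / p_LV), `wm_gm_ratio` (stiffness ratios).
#' @return A data.frame with columns `parameter`, `value`,
#'   `max_principal_strain` (signed), `max_abs_principal_strain`,
#'   `max_wall_displacement`, `converged`, sorted by parameter then value.
#' @export
run_sensitivity_sweep <- function(mesh, table, base_bcs, sweep,
                                  settings = solver_settings()) {
  stopifnot(length(sweep) > 0)
  p_lv0 <- base_bcs$pressure_loads$VENTRICULAR_WALL
  p_sas0 <- base_bcs$pressure_loads$GM_CSF_INTERFACE
  rows <- list()
  run_one <- function(parameter, value, bcs, tab) {
    sol <- tryCatch(solve_quasistatic(mesh, tab, bcs, settings), error = function(e) NULL)
    if (is.null(sol) || !sol$converged) {
      data.frame(parameter = parameter, value = value, max_principal_strain = NA,
                 max_abs_principal_strain = NA, max_wall_displacement = NA,
                 converged = FALSE)
    } else {
      ws <- wall_summary(mesh, sol)
      data.frame(parameter = parameter, value = value,
                 max_principal_strain = ws[["max_principal_strain"]],
                 max_abs_principal_strain = ws[["max_abs_principal_strain"]],
                 max_wall_displacement = ws[["max_wall_displacement"]],
                 converged = TRUE)
    }
  }
  for (p in sort(sweep$p_lv %||% numeric(0))) {
    bcs <- base_bcs
    bcs$pressure_loads$VENTRICULAR_WALL <- p
    bcs$pressure_loads$GM_CSF_INTERFACE <- p * (p_sas0 / p_lv0)
    rows[[length(rows) + 1L]] <- run_one("p_lv", p, bcs, table)
  }
  for (r in sort(sweep$p_ratio %||% numeric(0))) {
    bcs <- base_bcs
    bcs$pressure_loads$GM_CSF_INTERFACE <- r * p_lv0
    rows[[length(rows) + 1L]] <- run_one("p_ratio", r, bcs, table)
  }
  for (s in sort(sweep$wm_gm_ratio %||% numeric(0))) {
    rows[[length(rows) + 1L]] <- run_one("wm_gm_ratio", s, base_bcs,
                                         default_tissue_table(s))
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
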