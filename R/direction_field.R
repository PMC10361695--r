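# Auxiliary Laplacian "temperature" problem and per-wall-element frames.
#
# The wall-normal and tangential projection directions are obtained a priori
# on the reference configuration from a discrete harmonic field: T = 1 on the
# ventricular wall, T = 0.1 on the gray-matter/CSF interface, T = 0 on the
# outer surface. The (element-wise constant) gradient of T on the tets owning
# a wall face provides the wall normal n = -grad(T)/|grad(T)| pointing from
# the cavity into the tissue.

#' Solve the Laplace problem on the mesh
#'
#' Discrete harmonic scalar field with Dirichlet values fixed on the tagged
#' boundary node sets, assembled with the same linear tetrahedral shape
#' functions as the mechanical solver.
#'
#' @param mesh A [labeled_mesh()].
#' @param bc_values Named list of Dirichlet values per surface tag; tags
#'   absent from the list carry no constraint. Default: wall 1.0, GM-CSF
#'   interface 0.1, outer surface 0.0.
#' @return An object of class `scalar_field` with `nodal_T` (length N).
#' @export
solve_laplace <- function(mesh,
                          bc_values = list(VENTRICULAR_WALL = 1.0,
                                           GM_CSF_INTERFACE = 0.1,
                                           OUTER_SURFACE = 0.0)) {
  N <- nrow(mesh$nodes)
  sg <- tet_shape_gradients(mesh)
  M <- nrow(mesh$tets)
  ti <- tj <- vector("list", 16L)
  tx <- vector("list", 16L)
  q <- 0L
  for (a in 1:4) for (b in 1:4) {
    q <- q + 1L
    ti[[q]] <- mesh$tets[, a]
    tj[[q]] <- mesh$tets[, b]
    tx[[q]] <- sg$V * rowSums(sg$G[, a, , drop = FALSE] * sg$G[, b, , drop = FALSE])
  }
  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(N, N))
  Tvals <- rep(NA_real_, N)
  for (tag in names(bc_values)) {
    s <- mesh$surfaces[[tag]]
    if (is.null(s)) next
    Tvals[unique(as.vector(s))] <- bc_values[[tag]]
  }
  fixed <- which(!is.na(Tvals))
  if (!length(fixed))
    stop("solve_laplace: no Dirichlet nodes (none of the tags in bc_values exist on the mesh)")
  free <- setdiff(seq_len(N), fixed)
  Tn <- Tvals
  if (length(free)) {
    rhs <- -K[free, fixed, drop = FALSE] %*% Tvals[fixed]
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    Tn[free] <- as.numeric(Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE), rhs))
  }
  structure(list(nodal_T = Tn, bc_values = bc_values), class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("Scalar field on %d nodes, range [%.4g, %.4g]\n",
              length(x$nodal_T), min(x$nodal_T), max(x$nodal_T)))
  invisible(x)
}

#' Per-wall-element orthonormal frames from the Laplace gradient
#'
#' For every tetrahedron owning a `VENTRICULAR_WALL` face, the frame normal is
#' `n = -grad(T)/|grad(T)|` (T decreases away from the cavity, so n points
#' from the cavity into the tissue); `v1`, `v2` complete a right-handed
#' orthonormal triad (`v1 x v2 = n`). The gradient is the exact element-wise
#' constant gradient of the linear interpolant; no nodal smoothing is applied.
#'
#' @param field A [solve_laplace()] result on the same mesh.
#' @param mesh A [labeled_mesh()] with a `VENTRICULAR_WALL` surface.
#' @return An object of class `wall_frames`: list with `face` (wall triangle
#'   index), `tet` (owning tet index), and K x 3 matrices `n`, `v1`, `v2`.
#' @export
compute_wall_frames <- function(field, mesh) {
  stopifnot(inherits(field, "scalar_field"),
            length(field$nodal_T) == nrow(mesh$nodes))
  tris <- mesh$surfaces$VENTRICULAR_WALL
  if (is.null(tris)) stop("compute_wall_frames: mesh has no VENTRICULAR_WALL surface")
  own <- surface_owner_tets(mesh, "VENTRICULAR_WALL")
  sg <- tet_shape_gradients(mesh)
  K <- nrow(tris)
  n <- v1 <- v2 <- matrix(0, K, 3)
  Tn <- field$nodal_T
  for (q in seq_len(K)) {
    e <- own[q]
    Te <- Tn[mesh$tets[e, ]]
    g <- colSums(sg$G[e, , ] * Te)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12)
      stop(sprintf("compute_wall_frames: degenerate temperature gradient in element %d", e))
    nq <- -g / gn
    # orthonormal completion: start from the coordinate axis least aligned with n
    h <- diag(3)[, which.min(abs(nq))]
    t1 <- h - sum(h * nq) * nq
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(nq[2] * t1[3] - nq[3] * t1[2],
            nq[3] * t1[1] - nq[1] * t1[3],
            nq[1] * t1[2] - nq[2] * t1[1])
    n[q, ] <- nq; v1[q, ] <- t1; v2[q, ] <- t2
  }
  structure(list(face = seq_len(K), tet = own, n = n, v1 = v1, v2 = v2),
            class = "wall_frames")
}

#' @export
print.wall_frames <- function(x, ...) {
  cat(sprintf("Wall frames for %d wall faces\n", length(x$face)))
  invisible(x)
}
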