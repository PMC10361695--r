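# Deformation-based markers of ventricular wall loading: projection
# stretches of the right Cauchy-Green tensor onto the wall frame, the
# ependymal thinning ratio (tangential area change over normal thickness
# change), maximum principal strain, and displacement magnitude, aggregated
# from wall elements to wall nodes.

#' Projection stretches of a deformation gradient onto a wall frame
#'
#' With `C = F'F`, the normal stretch is `sqrt(n . C n)` and the extremal
#' tangential stretches are the square roots of the eigenvalues of the 2x2
#' restriction of C to the tangent plane spanned by `v1`, `v2` (so they are
#' invariant under rotations of the tangent basis about n).
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @param frame List or one-row frame with unit vectors `n`, `v1`, `v2`.
#' @return An object of class `stretch_triple`: list with `lambda_n`,
#'   `lambda_t_max`, `lambda_t_min`.
#' @export
project_stretches <- function(F, frame) {
  stopifnot(det(F) > 0)
  n <- as.numeric(frame$n); v1 <- as.numeric(frame$v1); v2 <- as.numeric(frame$v2)
  C <- crossprod(F)
  ln <- sqrt(as.numeric(n %*% C %*% n))
  Ct <- matrix(c(v1 %*% C %*% v1, v1 %*% C %*% v2,
                 v2 %*% C %*% v1, v2 %*% C %*% v2), 2, 2)
  ev <- eigen((Ct + t(Ct)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lt <- sqrt(pmax(ev, 0))
  structure(list(lambda_n = ln, lambda_t_max = lt[1], lambda_t_min = lt[2]),
            class = "stretch_triple")
}

#' @export
print.stretch_triple <- function(x, ...) {
  cat(sprintf("Stretches: lambda_n = %.5g, lambda_t_max = %.5g, lambda_t_min = %.5g\n",
              x$lambda_n, x$lambda_t_max, x$lambda_t_min))
  invisible(x)
}

#' Ependymal thinning ratio
#'
#' Tangential area change divided by normal (apical-basal) thickness change:
#' `T = (lambda_t_max * lambda_t_min) / lambda_n`. Equal to 1 in the
#' undeformed state; values above 1 indicate cells stretched thin.
#'
#' @param s A [project_stretches()] result (or any list with the three
#'   stretch fields).
#' @return Scalar thinning ratio.
#' @export
thinning_ratio <- function(s) {
  stopifnot(s$lambda_n > 0, s$lambda_t_max > 0, s$lambda_t_min > 0)
  (s$lambda_t_max * s$lambda_t_min) / s$lambda_n
}

#' Maximum principal strain
#'
#' Largest principal strain of the deformation, from the largest principal
#' stretch `lambda_max` of C: logarithmic `log(lambda_max)` (default),
#' Green-Lagrange `(lambda_max^2 - 1)/2`, or nominal `lambda_max - 1`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param measure Strain measure.
#' @return Scalar strain.
#' @export
max_principal_strain <- function(F, measure = c("logarithmic", "green", "nominal")) {
  measure <- match.arg(measure)
  stopifnot(det(F) > 0)
  lmax <- sqrt(max(eigen(crossprod(F), symmetric = TRUE, only.values = TRUE)$values))
  switch(measure,
         logarithmic = log(lmax),
         green = (lmax^2 - 1) / 2,
         nominal = lmax - 1)
}

#' Aggregate per-wall-element values to wall nodes
#'
#' Each wall node receives the area-weighted average (reference triangle
#' areas) of the values carried by its adjacent wall faces.
#'
#' @param values Numeric vector (one value per wall face) or matrix with one
#'   row per wall face.
#' @param mesh A [labeled_mesh()] with a `VENTRICULAR_WALL` surface.
#' @return For vector input, a named numeric vector indexed by global wall
#'   node id; for matrix input, a matrix with one row per wall node.
#' @export
aggregate_to_wall_nodes <- function(values, mesh) {
  tris <- mesh$surfaces$VENTRICULAR_WALL
  vec_in <- is.null(dim(values))
  vals <- if (vec_in) matrix(values, ncol = 1) else as.matrix(values)
  stopifnot(nrow(vals) == nrow(tris))
  area <- triangle_normals(mesh$nodes, tris)$area
  wn <- surface_nodes(mesh, "VENTRICULAR_WALL")
  wsum <- matrix(0, length(wn), ncol(vals))
  asum <- numeric(length(wn))
  idx <- match(as.vector(tris), wn)           # 3K node slots
  for (cpt in seq_len(ncol(vals))) {
    contrib <- rep(vals[, cpt] * area, 3L)
    wsum[, cpt] <- as.numeric(rowsum(contrib, idx, reorder = TRUE))
  }
  asum <- as.numeric(rowsum(rep(area, 3L), idx, reorder = TRUE))
  out <- wsum / asum
  rownames(out) <- wn
  if (vec_in) setNames(out[, 1], wn) else out
}

#' Compute all wall markers for a solved state
#'
#' Evaluates the projection stretches, thinning ratio, maximum principal
#' strain and displacement magnitude on every wall element (at its single
#' integration point) and aggregates them to wall nodes; attaches the
#' reference-configuration mean curvature, the WMH wall flag, and the pvWMH
#' thickness.
#'
#' @param mesh A [labeled_mesh()].
#' @param solution A [solve_quasistatic()] result on the same mesh.
#' @param frames A [compute_wall_frames()] result (reference configuration).
#' @param curvature Optional [mean_curvature_field()] result (computed if
#'   omitted).
#' @param strain_measure Strain measure for [max_principal_strain()].
#' @return An object of class `wall_markers`: a data.frame with one row per
#'   wall node (columns `node`, `x`, `y`, `z`, `lambda_n`, `lambda_t_max`,
#'   `lambda_t_min`, `thinning`, `max_principal_strain`,
#'   `displacement_magnitude`, `mean_curvature`, `wmh`, `wmh_thickness`).
#' @export
compute_wall_markers <- function(mesh, solution, frames, curvature = NULL,
                                 strain_measure = "logarithmic") {
  K <- length(frames$face)
  em <- matrix(0, K, 5)
  for (q in seq_len(K)) {
    F <- solution$element_F[, , frames$tet[q]]
    s <- project_stretches(F, list(n = frames$n[q, ], v1 = frames$v1[q, ],
                                   v2 = frames$v2[q, ]))
    em[q, ] <- c(s$lambda_n, s$lambda_t_max, s$lambda_t_min, thinning_ratio(s),
                 max_principal_strain(F, strain_measure))
  }
  agg <- aggregate_to_wall_nodes(em, mesh)
  wn <- as.integer(rownames(agg))
  if (is.null(curvature)) curvature <- mean_curvature_field(mesh)
  stopifnot(identical(curvature$node, wn))
  wmh <- map_wmh_to_wall(mesh)
  thick <- wmh_thickness(mesh, frames)
  um <- sqrt(rowSums(solution$nodal_displacements[wn, , drop = FALSE]^2))
  out <- data.frame(node = wn, x = mesh$nodes[wn, 1], y = mesh$nodes[wn, 2],
                    z = mesh$nodes[wn, 3], lambda_n = agg[, 1],
                    lambda_t_max = agg[, 2], lambda_t_min = agg[, 3],
                    thinning = agg[, 4], max_principal_strain = agg[, 5],
                    displacement_magnitude = um,
                    mean_curvature = curvature$K, wmh = wmh,
                    wmh_thickness = thick$thickness, row.names = NULL)
  class(out) <- c("wall_markers", "data.frame")
  out
}

#' @export
print.wall_markers <- function(x, ...) {
  cat(sprintf("Wall markers for %d wall nodes (%d WMH-flagged)\n", nrow(x), sum(x$wmh)))
  print.data.frame(head(as.data.frame(x), 4), digits = 4)
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4))
  invisible(x)
}
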