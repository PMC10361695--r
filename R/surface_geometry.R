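# Ventricular wall geometry: per-node principal curvatures by bi-quadratic
# surface patch fitting, and pvWMH thickness by casting the wall normal ray
# through the labeled tetrahedra.
#
# Curvature sign convention: the local height direction points toward the
# cavity, so regions that are convex as seen from inside the cavity (the horn
# tips) carry positive mean curvature. The principal-curvature formula is
# k1,2 = a + c +/- sqrt((a-c)^2 + 4 b^2), i.e. the eigenvalues of the full
# Hessian of the patch S(u,v) = a u^2 + 2 b u v + c v^2; under this
# convention a sphere of radius R (fit a = c = 1/(2R)) has curvature 1/R.

# wall surface with local indexing + vertex adjacency rings
wall_surface <- function(mesh) {
  tris_g <- mesh$surfaces$VENTRICULAR_WALL
  if (is.null(tris_g)) stop("wall_surface: mesh has no VENTRICULAR_WALL surface")
  wn <- sort(unique(as.vector(tris_g)))
  tris <- matrix(match(tris_g, wn), ncol = 3)
  nb <- vector("list", length(wn))
  for (q in seq_len(nrow(tris))) {
    t3 <- tris[q, ]
    nb[[t3[1]]] <- c(nb[[t3[1]]], t3[2:3])
    nb[[t3[2]]] <- c(nb[[t3[2]]], t3[c(1, 3)])
    nb[[t3[3]]] <- c(nb[[t3[3]]], t3[1:2])
  }
  nb <- lapply(nb, unique)
  tn <- triangle_normals(mesh$nodes, tris_g)
  list(nodes = wn, coords = mesh$nodes[wn, , drop = FALSE], tris = tris,
       tris_global = tris_g, neighbors = nb, face_n2A = tn$n2A, face_area = tn$area)
}

# ring-neighborhood of a local wall vertex
ring_neighbors <- function(ws, v, depth) {
  cur <- v
  seen <- v
  for (d in seq_len(depth)) {
    cur <- setdiff(unique(unlist(ws$neighbors[cur])), seen)
    seen <- c(seen, cur)
  }
  setdiff(seen, v)
}

# vertex normal toward the cavity (negated area-weighted face normals; wall
# faces are oriented away from the cavity)
wall_vertex_inward_normals <- function(ws) {
  nrm <- matrix(0, length(ws$nodes), 3)
  for (q in seq_len(nrow(ws$tris))) {
    for (v in ws$tris[q, ]) nrm[v, ] <- nrm[v, ] + ws$face_n2A[q, ]
  }
  -nrm / sqrt(rowSums(nrm^2))
}

fit_patch_local <- function(ws, v, inward_n, ring_depth = 1) {
  en <- inward_n[v, ]
  h <- diag(3)[, which.min(abs(en))]
  eu <- h - sum(h * en) * en
  eu <- eu / sqrt(sum(eu^2))
  ev <- c(en[2] * eu[3] - en[3] * eu[2],
          en[3] * eu[1] - en[1] * eu[3],
          en[1] * eu[2] - en[2] * eu[1])
  depth <- ring_depth
  repeat {
    nbr <- ring_neighbors(ws, v, depth)
    if (length(nbr) >= 5 || depth >= max(2, ring_depth)) break
    depth <- depth + 1
  }
  if (length(nbr) < 3)
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                n_neighbors = length(nbr), residual = NA_real_, flagged = TRUE,
                frame = list(e_u = eu, e_v = ev, e_n = en)))
  d <- ws$coords[nbr, , drop = FALSE] -
    matrix(ws$coords[v, ], length(nbr), 3, byrow = TRUE)
  u <- d %*% eu; vv <- d %*% ev; w <- d %*% en
  B <- cbind(u^2, 2 * u * vv, vv^2)
  qrB <- qr(B)
  if (qrB$rank < 3) {
    if (depth < 2) return(fit_patch_local(ws, v, inward_n, ring_depth = 2))
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                n_neighbors = length(nbr), residual = NA_real_, flagged = TRUE,
                frame = list(e_u = eu, e_v = ev, e_n = en)))
  }
  abc <- qr.coef(qrB, w)
  resid <- sqrt(mean((B %*% abc - w)^2))
  list(a = abc[1], b = abc[2], c = abc[3], n_neighbors = length(nbr),
       residual = resid, flagged = FALSE,
       frame = list(e_u = eu, e_v = ev, e_n = en))
}

#' Fit a bi-quadratic surface patch at a wall node
#'
#' Expresses the neighboring wall nodes (1-ring, extended to the 2-ring when
#' fewer than 5 neighbors are available) in a local frame whose height axis is
#' the inward (toward-cavity) area-weighted vertex normal, and solves the
#' least-squares fit of `S(u,v) = a u^2 + 2 b u v + c v^2` to the neighbor
#' heights.
#'
#' @param node Global node id on the ventricular wall.
#' @param mesh A [labeled_mesh()].
#' @param ring_depth Starting neighborhood ring depth (default 1).
#' @return A list with `a`, `b`, `c` (1/mm scale), `n_neighbors`, `residual`
#'   (mm), `flagged` (TRUE when the fit is rank-deficient), `frame`.
#' @export
fit_patch <- function(node, mesh, ring_depth = 1) {
  ws <- wall_surface(mesh)
  v <- match(node, ws$nodes)
  if (is.na(v)) stop("fit_patch: node ", node, " is not on the ventricular wall")
  inward <- wall_vertex_inward_normals(ws)
  fit_patch_local(ws, v, inward, ring_depth)
}

#' Principal curvatures from a patch fit
#'
#' `k1 = a + c + sqrt((a - c)^2 + 4 b^2)` and `k2` with the minus sign —
#' the eigenvalues of the full patch Hessian `[[2a, 2b], [2b, 2c]]`, ordered
#' `k1 >= k2`.
#'
#' @param fit A [fit_patch()] result (or any list with `a`, `b`, `c`).
#' @return Numeric vector `c(k1, k2)` in 1/mm.
#' @export
principal_curvatures <- function(fit) {
  r <- sqrt((fit$a - fit$c)^2 + 4 * fit$b^2)
  c(k1 = fit$a + fit$c + r, k2 = fit$a + fit$c - r)
}

#' Mean curvature over the ventricular wall
#'
#' Fits a patch at every wall node and returns principal and mean curvatures
#' `K = (k1 + k2) / 2`. Rank-deficient fits propagate as NA.
#'
#' @param mesh A [labeled_mesh()].
#' @param ring_depth Starting ring depth for the patch fits.
#' @return An object of class `curvature_field`: data.frame with `node`
#'   (global id), `k1`, `k2`, `K` (1/mm), `flagged`.
#' @export
mean_curvature_field <- function(mesh, ring_depth = 1) {
  ws <- wall_surface(mesh)
  inward <- wall_vertex_inward_normals(ws)
  n <- length(ws$nodes)
  k1 <- k2 <- numeric(n)
  fl <- logical(n)
  for (v in seq_len(n)) {
    f <- fit_patch_local(ws, v, inward, ring_depth)
    if (f$flagged) { k1[v] <- NA; k2[v] <- NA; fl[v] <- TRUE; next }
    kk <- principal_curvatures(f)
    k1[v] <- kk[1]; k2[v] <- kk[2]
  }
  out <- data.frame(node = ws$nodes, k1 = k1, k2 = k2, K = (k1 + k2) / 2,
                    flagged = fl)
  class(out) <- c("curvature_field", "data.frame")
  out
}

# map from face key to the tets sharing that face (built once per mesh call)
tet_face_map <- function(mesh) {
  tf <- tet_faces(mesh$tets)
  split(tf$tet, face_key(tf$faces))
}

#' Mark wall nodes overlapped by WMH elements
#'
#' A wall node is marked when it belongs to at least one wall face whose
#' owning tetrahedron, or a tetrahedron face-adjacent to it, carries the WMH
#' label.
#'
#' @param mesh A [labeled_mesh()] with region labels.
#' @return Logical vector over the wall nodes (in [surface_nodes()] order).
#' @export
map_wmh_to_wall <- function(mesh) {
  ws <- wall_surface(mesh)
  out <- logical(length(ws$nodes))
  if (!any(mesh$region == "WMH")) return(setNames(out, ws$nodes))
  own <- surface_owner_tets(mesh, "VENTRICULAR_WALL")
  fmap <- tet_face_map(mesh)
  is_wmh <- mesh$region == "WMH"
  face_marked <- logical(nrow(ws$tris))
  for (q in seq_along(own)) {
    e <- own[q]
    if (is_wmh[e]) { face_marked[q] <- TRUE; next }
    keys <- face_key(tet_faces(mesh$tets[e, , drop = FALSE])$faces)
    adj <- setdiff(unique(unlist(fmap[keys], use.names = FALSE)), e)
    if (any(is_wmh[adj])) face_marked[q] <- TRUE
  }
  for (q in which(face_marked)) out[ws$tris[q, ]] <- TRUE
  setNames(out, ws$nodes)
}

#' pvWMH thickness by normal-ray casting
#'
#' For every WMH-overlapping wall node, the outward wall normal ray (averaged
#' from the Laplace-field frames of the adjacent wall elements) is intersected
#' with the tetrahedra; the traversal stops at the first intersected element
#' that is not WMH-labeled, and the thickness is the maximum distance from the
#' wall node to the four vertices of the furthest WMH element intersected.
#' Nodes not overlapping a WMH get thickness zero. Rays that exit the mesh
#' while still inside WMH tissue are flagged.
#'
#' @param mesh A [labeled_mesh()] with WMH labels.
#' @param frames A [compute_wall_frames()] result (supplies the wall normals).
#' @return An object of class `thickness_field`: data.frame with `node`
#'   (global wall node ids), `thickness` (mm), `flagged`.
#' @export
wmh_thickness <- function(mesh, frames) {
  ws <- wall_surface(mesh)
  wmh_node <- map_wmh_to_wall(mesh)
  nW <- length(ws$nodes)
  thick <- numeric(nW)
  flag <- logical(nW)
  if (!any(wmh_node)) {
    out <- data.frame(node = ws$nodes, thickness = thick, flagged = flag)
    class(out) <- c("thickness_field", "data.frame")
    return(out)
  }
  # per-node outward normal from the adjacent wall-face frames
  nrm <- matrix(0, nW, 3)
  for (q in seq_len(nrow(ws$tris)))
    for (v in ws$tris[q, ]) nrm[v, ] <- nrm[v, ] + frames$n[q, ]
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # tet geometry for interval clipping
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
          mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  rad2 <- numeric(nrow(mesh$tets))
  for (a in 1:4)
    rad2 <- pmax(rad2, rowSums((mesh$nodes[mesh$tets[, a], , drop = FALSE] - cen)^2))
  rad <- sqrt(rad2)
  sg <- tet_shape_gradients(mesh)
  is_wmh <- mesh$region == "WMH"
  eps <- 1e-9 * max(rad)
  for (v in which(wmh_node)) {
    x0 <- ws$coords[v, ]
    d <- nrm[v, ]
    w <- cen - matrix(x0, nrow(cen), 3, byrow = TRUE)
    tp <- as.numeric(w %*% d)
    perp2 <- rowSums(w^2) - tp^2
    cand <- which(perp2 <= rad2 * (1 + 1e-9) & tp >= -rad)
    if (!length(cand)) next
    tin <- rep(-Inf, length(cand)); tout <- rep(Inf, length(cand))
    for (a in 1:4) {
      Ga <- sg$G[cand, a, , drop = FALSE]
      dim(Ga) <- c(length(cand), 3)
      slope <- as.numeric(Ga %*% d)
      # lambda_a(x0): affine shape value at ray origin
      X1 <- mesh$nodes[mesh$tets[cand, 1], , drop = FALSE]
      r0 <- matrix(x0, length(cand), 3, byrow = TRUE) - X1
      val0 <- rowSums(Ga * r0) + as.numeric(a == 1)
      lo <- ifelse(slope > 0, -val0 / slope, -Inf)
      hi <- ifelse(slope < 0, -val0 / slope, Inf)
      zero_bad <- slope == 0 & val0 < 0
      tin <- pmax(tin, lo); tout <- pmin(tout, hi)
      tout[zero_bad] <- -Inf
    }
    hit <- tout > pmax(tin, 0) + eps
    if (!any(hit)) next
    ord <- order(pmax(tin[hit], 0))
    tets_hit <- cand[hit][ord]
    last_wmh <- 0L
    exited_in_wmh <- TRUE
    for (e in tets_hit) {
      if (is_wmh[e]) last_wmh <- e
      else { exited_in_wmh <- FALSE; break }
    }
    if (last_wmh == 0L) next
    verts <- mesh$nodes[mesh$tets[last_wmh, ], , drop = FALSE]
    thick[v] <- sqrt(max(rowSums((verts - matrix(x0, 4, 3, byrow = TRUE))^2)))
    flag[v] <- exited_in_wmh
  }
  out <- data.frame(node = ws$nodes, thickness = thick, flagged = flag)
  class(out) <- c("thickness_field", "data.frame")
  out
}
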