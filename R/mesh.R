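# Labeled tetrahedral mesh container and geometric utilities.
#
# Conventions:
#  - nodes: N x 3 matrix of coordinates in mm.
#  - tets:  M x 4 integer matrix of node indices, positively oriented
#           (signed volume > 0).
#  - region: length-M character vector with values in {WM, GM, SAS, WMH}.
#  - surfaces: named list of K x 3 integer triangle matrices. Each triangle is
#    oriented so that its right-hand normal points in the direction a surface
#    pressure on that tag would act (into the loaded tissue): the ventricular
#    wall normal points away from the cavity into white matter, the GM-CSF
#    interface normal points inward into gray matter, the outer surface is
#    oriented outward (it is fixed, so its orientation is only used for
#    geometric checks).

REGION_LEVELS <- c("WM", "GM", "SAS", "WMH")
SURFACE_TAGS <- c("VENTRICULAR_WALL", "GM_CSF_INTERFACE", "OUTER_SURFACE")

#' Construct a labeled tetrahedral mesh
#'
#' @param nodes N x 3 numeric matrix of node coordinates (mm).
#' @param tets M x 4 integer matrix of tetrahedra (1-based node indices).
#' @param region Character vector of length M with element region labels
#'   (subset of `WM`, `GM`, `SAS`, `WMH`).
#' @param surfaces Named list of K x 3 integer triangle matrices (tagged
#'   boundary surfaces).
#' @param validate Run consistency checks (positive volumes, index ranges).
#' @return An object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(nodes, tets, region, surfaces = list(), validate = TRUE) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  region <- as.character(region)
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4, length(region) == nrow(tets))
  m <- structure(list(nodes = nodes, tets = tets, region = region,
                      surfaces = lapply(surfaces, function(s) {
                        s <- as.matrix(s); storage.mode(s) <- "integer"; s
                      })),
                 class = "labeled_mesh")
  if (validate) {
    if (nrow(tets) > 0) {
      if (min(tets) < 1 || max(tets) > nrow(nodes)) stop("labeled_mesh: tet node index out of range")
      v <- tet_volumes(m)
      if (any(v <= 0)) stop(sprintf("labeled_mesh: %d tetrahedra have non-positive volume", sum(v <= 0)))
    }
    bad <- setdiff(unique(region), REGION_LEVELS)
    if (length(bad)) stop("labeled_mesh: unknown region labels: ", paste(bad, collapse = ", "))
    for (nm in names(m$surfaces)) {
      s <- m$surfaces[[nm]]
      if (nrow(s) && (min(s) < 1 || max(s) > nrow(nodes)))
        stop("labeled_mesh: surface '", nm, "' node index out of range")
    }
  }
  m
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("Labeled tetrahedral mesh: %d nodes, %d tets\n", nrow(x$nodes), nrow(x$tets)))
  tb <- table(factor(x$region, levels = REGION_LEVELS))
  cat("  regions: ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n", sep = "")
  for (nm in names(x$surfaces))
    cat(sprintf("  surface %-18s %d triangles\n", nm, nrow(x$surfaces[[nm]])))
  invisible(x)
}

#' Signed tetrahedron volumes
#' @param mesh A [labeled_mesh()].
#' @return Numeric vector of signed volumes (mm^3), positive for valid meshes.
#' @export
tet_volumes <- function(mesh) {
  x <- mesh$nodes; t <- mesh$tets
  a <- x[t[, 2], , drop = FALSE] - x[t[, 1], , drop = FALSE]
  b <- x[t[, 3], , drop = FALSE] - x[t[, 1], , drop = FALSE]
  c <- x[t[, 4], , drop = FALSE] - x[t[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
   a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

# Per-triangle (non-unit) normals n*2A and areas for a triangle matrix on
# given coordinates; right-hand rule on the stored vertex order.
triangle_normals <- function(nodes, tris) {
  a <- nodes[tris[, 2], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 3], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  n2A <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  list(n2A = n2A, area = 0.5 * sqrt(rowSums(n2A^2)))
}

#' Areas of a tagged surface
#' @param mesh A [labeled_mesh()].
#' @param tag Surface tag name.
#' @return Numeric vector of triangle areas (mm^2).
#' @export
surface_areas <- function(mesh, tag) {
  triangle_normals(mesh$nodes, mesh$surfaces[[tag]])$area
}

# Key encoding for faces (sorted node triples) as strings; used for
# face-to-tet maps and watertightness checks.
face_key <- function(tris) {
  s <- apply(tris, 1L, function(f) paste(sort.int(f), collapse = "_"))
  as.character(s)
}

# All 4 faces of every tet, with owning tet index. Face a: opposite node a.
tet_faces <- function(tets) {
  M <- nrow(tets)
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
             tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  list(faces = f, tet = rep.int(seq_len(M), 4L))
}

#' Map tagged surface triangles to their owning tetrahedra
#'
#' Each triangle of a tagged boundary surface borders exactly one tetrahedron
#' of the adjacent region; this returns that tet index per triangle.
#'
#' @param mesh A [labeled_mesh()].
#' @param tag Surface tag name.
#' @return Integer vector, one owning tet per surface triangle.
#' @export
surface_owner_tets <- function(mesh, tag) {
  tris <- mesh$surfaces[[tag]]
  if (is.null(tris)) stop("surface_owner_tets: no surface tagged '", tag, "'")
  tf <- tet_faces(mesh$tets)
  keys <- face_key(tf$faces)
  cnt <- table(keys)
  skey <- face_key(tris)
  # boundary faces appear exactly once among tet faces
  idx <- match(skey, keys)
  if (anyNA(idx)) stop("surface_owner_tets: surface face not found among tet faces")
  multi <- cnt[skey] > 1
  if (any(multi)) {
    # interior interface (e.g. GM-CSF): pick the owner on the loaded side,
    # i.e. the tet whose outward face normal matches the stored orientation.
    ord <- order(keys)
    sk <- keys[ord]
    first <- match(skey, sk)
    out <- integer(nrow(tris))
    for (q in seq_len(nrow(tris))) {
      hits <- ord[seq(first[q], length.out = cnt[[skey[q]]])]
      owners <- tf$tet[hits]
      if (length(owners) == 1) { out[q] <- owners; next }
      # choose owner for which the stored triangle normal points away from it
      tri <- tris[q, ]
      nrm <- triangle_normals(mesh$nodes, matrix(tri, 1))$n2A[1, ]
      cface <- colMeans(mesh$nodes[tri, , drop = FALSE])
      pick <- owners[1]
      for (ow in owners) {
        copp <- colMeans(mesh$nodes[mesh$tets[ow, ], , drop = FALSE])
        if (sum((cface - copp) * nrm) > 0) { pick <- ow; break }
      }
      out[q] <- pick
    }
    return(out)
  }
  tf$tet[idx]
}

#' Boundary edges of a triangulated surface
#'
#' An edge of a closed (watertight) orientable surface is shared by exactly
#' two triangles; this returns the edges used by an odd number of triangles
#' (empty for a closed surface).
#'
#' @param tris K x 3 triangle matrix.
#' @return Two-column matrix of boundary edges (node index pairs).
#' @export
surface_boundary_edges <- function(tris) {
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2], sep = "_")
  tb <- table(key)
  odd <- names(tb)[tb %% 2L == 1L]
  if (!length(odd)) return(matrix(integer(), 0, 2))
  do.call(rbind, lapply(strsplit(odd, "_"), as.integer))
}

#' Enclosed volume of a closed oriented surface
#'
#' Divergence-theorem volume `sum x1 . (x2 x x3) / 6` over the triangles.
#' With outward-oriented triangles this is the (positive) enclosed volume;
#' used to measure the ventricular cavity volume from the wall surface, whose
#' stored orientation points away from the cavity.
#'
#' @param nodes Node coordinate matrix.
#' @param tris Oriented triangle matrix.
#' @return Signed volume (mm^3).
#' @export
enclosed_volume <- function(nodes, tris) {
  x1 <- nodes[tris[, 1], , drop = FALSE]
  x2 <- nodes[tris[, 2], , drop = FALSE]
  x3 <- nodes[tris[, 3], , drop = FALSE]
  cr <- cbind(x2[, 2] * x3[, 3] - x2[, 3] * x3[, 2],
              x2[, 3] * x3[, 1] - x2[, 1] * x3[, 3],
              x2[, 1] * x3[, 2] - x2[, 2] * x3[, 1])
  sum(rowSums(x1 * cr)) / 6
}

#' Ventricular cavity volume
#'
#' @param mesh A [labeled_mesh()] with a `VENTRICULAR_WALL` surface.
#' @param displacements Optional N x 3 nodal displacement matrix; if given the
#'   deformed cavity volume is returned.
#' @return Cavity volume in mm^3.
#' @export
cavity_volume <- function(mesh, displacements = NULL) {
  x <- mesh$nodes
  if (!is.null(displacements)) x <- x + displacements
  enclosed_volume(x, mesh$surfaces$VENTRICULAR_WALL)
}

# Per-tet shape-function gradients and volumes for linear tetrahedra.
# Returns G: M x 4 x 3 array (dN_a/dX_j constant per tet) and V: volumes.
tet_shape_gradients <- function(mesh) {
  x <- mesh$nodes; t <- mesh$tets; M <- nrow(t)
  a <- x[t[, 2], , drop = FALSE] - x[t[, 1], , drop = FALSE]
  b <- x[t[, 3], , drop = FALSE] - x[t[, 1], , drop = FALSE]
  c <- x[t[, 4], , drop = FALSE] - x[t[, 1], , drop = FALSE]
  # det and inverse of D = [a b c] (columns), vectorized
  d1 <- b[, 2] * c[, 3] - b[, 3] * c[, 2]
  d2 <- b[, 3] * c[, 1] - b[, 1] * c[, 3]
  d3 <- b[, 1] * c[, 2] - b[, 2] * c[, 1]
  det <- a[, 1] * d1 + a[, 2] * d2 + a[, 3] * d3
  # rows of D^{-1} are gradients of barycentric coords 2..4
  # D^{-1} = adj(D)/det ; adj rows: (b x c; c x a; a x b)
  r2 <- cbind(d1, d2, d3) / det
  r3 <- cbind(c[, 2] * a[, 3] - c[, 3] * a[, 2],
              c[, 3] * a[, 1] - c[, 1] * a[, 3],
              c[, 1] * a[, 2] - c[, 2] * a[, 1]) / det
  r4 <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1]) / det
  G <- array(0, c(M, 4, 3))
  G[, 2, ] <- r2; G[, 3, ] <- r3; G[, 4, ] <- r4
  G[, 1, ] <- -(r2 + r3 + r4)
  list(G = G, V = det / 6)
}

# ---------------------------------------------------------------------------
# Structured meshes used for verification (patch tests, slabs).

#' Structured tetrahedral box mesh
#'
#' A `nx x ny x nz` grid of cubes, each split into six tetrahedra (Kuhn
#' subdivision, conforming across cubes). Face tags `XMIN`, `XMAX`, `YMIN`,
#' `YMAX`, `ZMIN`, `ZMAX` are stored with triangle normals oriented into the
#' box, so a pressure load on any tag pushes into the body.
#'
#' @param nx,ny,nz Number of cells per direction.
#' @param lx,ly,lz Edge lengths (mm).
#' @param region Region label for all elements (default "GM").
#' @param origin Corner position (mm).
#' @return A [labeled_mesh()].
#' @export
box_mesh <- function(nx = 2, ny = 2, nz = 2, lx = 1, ly = 1, lz = 1,
                     region = "GM", origin = c(0, 0, 0)) {
  gx <- seq(0, lx, length.out = nx + 1) + origin[1]
  gy <- seq(0, ly, length.out = ny + 1) + origin[2]
  gz <- seq(0, lz, length.out = nz + 1) + origin[3]
  nid <- function(i, j, k) i + (nx + 1L) * ((j - 1L) + (ny + 1L) * (k - 1L))
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  colnames(nodes) <- NULL
  # Kuhn subdivision of the unit cube: 6 tets around diagonal (0,0,0)-(1,1,1)
  corners <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0),
                   c(0,0,1), c(1,0,1), c(0,1,1), c(1,1,1))
  kuhn <- rbind(c(1,2,4,8), c(1,4,3,8), c(1,3,7,8),
                c(1,7,5,8), c(1,5,6,8), c(1,6,2,8))
  tets <- matrix(0L, 6L * nx * ny * nz, 4L)
  q <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    ids <- nid(i + corners[, 1], j + corners[, 2], k + corners[, 3])
    for (s in 1:6) { q <- q + 1L; tets[q, ] <- ids[kuhn[s, ]] }
  }
  m <- labeled_mesh(nodes, tets, rep(region, nrow(tets)), validate = FALSE)
  # fix orientation
  v <- tet_volumes(m)
  flip <- v < 0
  if (any(flip)) { tmp <- tets[flip, 3]; tets[flip, 3] <- tets[flip, 4]; tets[flip, 4] <- tmp }
  # boundary faces from quad grids, oriented into the box
  quads_to_tris <- function(q4) rbind(q4[, c(1, 2, 3)], q4[, c(1, 3, 4)])
  face_quads <- function(fix, dir) {
    # fix: which index fixed at min/max; dir in {"x","y","z"}
    qs <- NULL
    if (dir == "x") {
      i <- fix
      for (k in seq_len(nz)) for (j in seq_len(ny))
        qs <- rbind(qs, c(nid(i, j, k), nid(i, j + 1, k), nid(i, j + 1, k + 1), nid(i, j, k + 1)))
    } else if (dir == "y") {
      j <- fix
      for (k in seq_len(nz)) for (i in seq_len(nx))
        qs <- rbind(qs, c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j, k + 1), nid(i, j, k + 1)))
    } else {
      k <- fix
      for (j in seq_len(ny)) for (i in seq_len(nx))
        qs <- rbind(qs, c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k), nid(i, j + 1, k)))
    }
    qs
  }
  orient_into <- function(tris, inward) {
    # flip triangles whose normal does not point along `inward`
    nn <- triangle_normals(nodes, tris)$n2A
    flip <- (nn %*% inward) < 0
    tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
    tris
  }
  surfaces <- list(
    XMIN = orient_into(quads_to_tris(face_quads(1L, "x")), c(1, 0, 0)),
    XMAX = orient_into(quads_to_tris(face_quads(nx + 1L, "x")), c(-1, 0, 0)),
    YMIN = orient_into(quads_to_tris(face_quads(1L, "y")), c(0, 1, 0)),
    YMAX = orient_into(quads_to_tris(face_quads(ny + 1L, "y")), c(0, -1, 0)),
    ZMIN = orient_into(quads_to_tris(face_quads(1L, "z")), c(0, 0, 1)),
    ZMAX = orient_into(quads_to_tris(face_quads(nz + 1L, "z")), c(0, 0, -1)))
  labeled_mesh(nodes, tets, rep(region, nrow(tets)), surfaces)
}

#' Spherical shell verification mesh
#'
#' Concentric spherical shell (inner radius `a`, outer radius `b`) built by
#' radial extrusion of a subdivided icosphere, used for the pressurized
#' thick-sphere and harmonic-field verification problems. The inner surface
#' is tagged `VENTRICULAR_WALL` (normals outward, i.e. into the tissue, so an
#' inner pressure load inflates the shell) and the outer surface
#' `OUTER_SURFACE`.
#'
#' @param a,b Inner and outer radius (mm), `0 < a < b`.
#' @param n_layers Number of radial element layers.
#' @param level Icosphere subdivision level (4^level * 20 surface triangles).
#' @param region Region label for all elements (default "WM").
#' @return A [labeled_mesh()].
#' @export
spherical_shell_mesh <- function(a, b, n_layers = 6, level = 3, region = "WM") {
  stopifnot(a > 0, b > a, n_layers >= 1)
  ico <- icosphere(level)
  nv <- nrow(ico$verts)
  radii <- seq(a, b, length.out = n_layers + 1)
  nodes <- do.call(rbind, lapply(radii, function(r) ico$verts * r))
  tets <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    bot <- (l - 1L) * nv
    tets[[l]] <- split_prisms(cbind(ico$faces + bot, ico$faces + bot + nv))
  }
  tets <- do.call(rbind, tets)
  m0 <- labeled_mesh(nodes, tets, rep(region, nrow(tets)), validate = FALSE)
  v <- tet_volumes(m0)
  flip <- v < 0
  if (any(flip)) { tmp <- tets[flip, 3]; tets[flip, 3] <- tets[flip, 4]; tets[flip, 4] <- tmp }
  labeled_mesh(nodes, tets, rep(region, nrow(tets)),
               surfaces = list(VENTRICULAR_WALL = ico$faces,
                               OUTER_SURFACE = ico$faces + nv * n_layers))
}

#' Nodes lying on a tagged surface
#' @param mesh A [labeled_mesh()].
#' @param tag Surface tag name.
#' @return Sorted integer vector of node indices.
#' @export
surface_nodes <- function(mesh, tag) {
  s <- mesh$surfaces[[tag]]
  if (is.null(s)) stop("surface_nodes: no surface tagged '", tag, "'")
  sort(unique(as.vector(s)))
}

# ---------------------------------------------------------------------------
# Prism-to-tet subdivision (Dompierre et al. rule: conforming because every
# quad face is split along the diagonal through its smallest global node id).

# ids: k x 6 matrix, bottom (1,2,3), top (4,5,6) with 4 above 1.
split_prisms <- function(ids) {
  rot <- c(2, 3, 1, 5, 6, 4)
  flp <- c(4, 6, 5, 1, 3, 2)
  out <- matrix(0L, 3L * nrow(ids), 4L)
  for (q in seq_len(nrow(ids))) {
    w <- ids[q, ]
    pos <- which.min(w)
    if (pos > 3) { w <- w[flp]; pos <- which.min(w) }
    while (pos != 1) { w <- w[rot]; pos <- pos - 1L }
    if (min(w[2], w[6]) < min(w[3], w[5])) {
      t3 <- rbind(w[c(1, 2, 3, 6)], w[c(1, 2, 6, 5)], w[c(1, 5, 6, 4)])
    } else {
      t3 <- rbind(w[c(1, 2, 3, 5)], w[c(1, 5, 3, 6)], w[c(1, 5, 6, 4)])
    }
    out[(3 * q - 2):(3 * q), ] <- t3
  }
  out
}
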