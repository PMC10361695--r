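# Group classification of wall nodes (WMH vs adjacent healthy wall), the
# pooled two-sample t comparison, percent-elevation summaries, and the
# end-to-end pipeline driver.

# logical per wall face: face overlaps WMH (owning tet or a face-adjacent tet
# carries the WMH label)
wall_face_wmh <- function(mesh) {
  ws <- wall_surface(mesh)
  marked <- logical(nrow(ws$tris))
  if (!any(mesh$region == "WMH")) return(marked)
  own <- surface_owner_tets(mesh, "VENTRICULAR_WALL")
  fmap <- tet_face_map(mesh)
  is_wmh <- mesh$region == "WMH"
  for (q in seq_along(own)) {
    e <- own[q]
    if (is_wmh[e]) { marked[q] <- TRUE; next }
    keys <- face_key(tet_faces(mesh$tets[e, , drop = FALSE])$faces)
    adj <- setdiff(unique(unlist(fmap[keys], use.names = FALSE)), e)
    if (any(is_wmh[adj])) marked[q] <- TRUE
  }
  marked
}

# wall-face adjacency by shared edges: list of integer vectors per face
wall_face_adjacency <- function(tris) {
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2], sep = "_")
  fid <- rep(seq_len(nrow(tris)), 3L)
  groups <- split(fid, key)
  adj <- vector("list", nrow(tris))
  for (g in groups) if (length(g) == 2) {
    adj[[g[1]]] <- c(adj[[g[1]]], g[2])
    adj[[g[2]]] <- c(adj[[g[2]]], g[1])
  }
  adj
}

#' Classify wall nodes into WMH and adjacent groups
#'
#' The first group contains the nodes of all wall faces that overlap WMH
#' elements. The second group contains the nodes of wall faces within `rings`
#' edge-adjacency rings of the WMH faces (the faces adjacent to a WMH face,
#' then the faces adjacent to those, repeated `rings` times), excluding the
#' first group's nodes. Nodes of the remaining wall belong to neither group.
#'
#' @param mesh A [labeled_mesh()] with WMH labels.
#' @param rings Number of adjacency-ring expansions (default 2).
#' @return An object of class `node_groups`: list with integer vectors
#'   `wmh_nodes`, `adjacent_nodes` (global node ids) and `rings`.
#' @export
classify_wall_nodes <- function(mesh, rings = 2) {
  ws <- wall_surface(mesh)
  marked <- wall_face_wmh(mesh)
  adj <- wall_face_adjacency(ws$tris)
  current <- which(marked)
  seen <- marked
  ring_faces <- integer(0)
  if (rings > 0) for (r in seq_len(rings)) {
    nxt <- setdiff(unique(unlist(adj[current], use.names = FALSE)), which(seen))
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    ring_faces <- c(ring_faces, nxt)
    current <- nxt
  }
  wmh_nodes <- sort(unique(as.vector(ws$tris_global[marked, , drop = FALSE])))
  adj_nodes <- sort(setdiff(unique(as.vector(ws$tris_global[ring_faces, , drop = FALSE])),
                            wmh_nodes))
  structure(list(wmh_nodes = wmh_nodes, adjacent_nodes = adj_nodes, rings = rings),
            class = "node_groups")
}

#' @export
print.node_groups <- function(x, ...) {
  cat(sprintf("Wall node groups: %d WMH nodes, %d adjacent nodes (%d rings)\n",
              length(x$wmh_nodes), length(x$adjacent_nodes), x$rings))
  invisible(x)
}

#' Two-sample t test
#'
#' Pooled-variance (Student) two-sided test by default, with integer degrees
#' of freedom `n1 + n2 - 2`; Welch's unequal-variance test available via
#' `welch = TRUE`.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @param welch Use Welch's test instead of the pooled test.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("two_sample_t: both groups need at least 2 values")
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 <= 0) stop("two_sample_t: zero variance in both groups")
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 <= 0) stop("two_sample_t: zero pooled variance")
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Marker elevations in WMH versus adjacent wall regions
#'
#' For maximum principal strain, thinning ratio and mean curvature: group
#' means and SDs, the two-sample test, and the percent elevation
#' `(mean_WMH / mean_adjacent - 1) * 100`.
#'
#' @param markers A [compute_wall_markers()] data.frame.
#' @param groups A [classify_wall_nodes()] result.
#' @param welch Use Welch's test (default FALSE: pooled, integer df).
#' @return An object of class `group_stats`: data.frame with one row per
#'   marker (`marker`, `mean_wmh`, `sd_wmh`, `mean_adj`, `sd_adj`, `t`, `df`,
#'   `p`, `pct_elevation`).
#' @export
percent_elevations <- function(markers, groups, welch = FALSE) {
  if (!length(groups$wmh_nodes) || !length(groups$adjacent_nodes))
    stop("percent_elevations: empty node group (WMH: ", length(groups$wmh_nodes),
         ", adjacent: ", length(groups$adjacent_nodes), ")")
  sel <- c(max_principal_strain = "max_principal_strain",
           thinning_ratio = "thinning", mean_curvature = "mean_curvature")
  rows <- lapply(names(sel), function(mk) {
    col <- sel[[mk]]
    va <- markers[[col]][match(groups$wmh_nodes, markers$node)]
    vb <- markers[[col]][match(groups$adjacent_nodes, markers$node)]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    tt <- two_sample_t(va, vb, welch = welch)
    data.frame(marker = mk, mean_wmh = mean(va), sd_wmh = sd(va),
               mean_adj = mean(vb), sd_adj = sd(vb), t = tt$t, df = tt$df,
               p = tt$p, pct_elevation = (mean(va) / mean(vb) - 1) * 100)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_stats", "data.frame")
  out
}

#' @export
print.group_stats <- function(x, ...) {
  cat("WMH vs adjacent wall group statistics:\n")
  df <- as.data.frame(x)
  df$p <- signif(df$p, 3)
  print.data.frame(df, digits = 4, row.names = FALSE)
  invisible(x)
}
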