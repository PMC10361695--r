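# Intensity-threshold WMH segmentation: voxels of the whole-brain mask whose
# intensity exceeds mean + k * SD (naive statistics over the mask, sample SD),
# followed by removal of connected components that are predominantly adjacent
# to CSF (the rule used to delete septum and choroid plexus).

#' Intensity statistics over the whole-brain mask
#'
#' Mean and sample standard deviation (denominator n - 1) of the intensities
#' inside the brain mask Omega.
#'
#' @param vol An [intensity_volume()].
#' @param k Threshold multiplier stored alongside the statistics (default 2.5).
#' @return An object of class `mask_stats` with `mu_I`, `sigma_I`, `k`, `n`.
#' @export
estimate_stats <- function(vol, k = 2.5) {
  stopifnot(inherits(vol, "intensity_volume"), k > 0)
  v <- vol$voxels[vol$brain_mask]
  if (!length(v)) stop("estimate_stats: empty brain mask")
  structure(list(mu_I = mean(v), sigma_I = sd(v), k = k, n = length(v)),
            class = "mask_stats")
}

#' @export
print.mask_stats <- function(x, ...) {
  cat(sprintf("Mask statistics: mu = %.4g, sigma = %.4g (n = %d), k = %g\n",
              x$mu_I, x$sigma_I, x$n, x$k))
  invisible(x)
}

#' Threshold segmentation of hyperintense voxels
#'
#' Mask of brain-mask voxels with intensity strictly above
#' `mu_I + k * sigma_I`.
#'
#' @param vol An [intensity_volume()].
#' @param stats An [estimate_stats()] result (computed from `vol` when
#'   omitted).
#' @return An object of class `wmh_mask`: list with logical array `mask` and
#'   `provenance` (k, components_removed).
#' @export
threshold_mask <- function(vol, stats = estimate_stats(vol)) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(stats, "mask_stats"))
  if (!is.finite(stats$sigma_I) || stats$sigma_I <= 0)
    stop("threshold_mask: sigma_I must be positive (constant intensity volume?)")
  m <- vol$brain_mask & (vol$voxels > stats$mu_I + stats$k * stats$sigma_I)
  structure(list(mask = m,
                 provenance = list(k = stats$k, components_removed = FALSE)),
            class = "wmh_mask")
}

#' @export
print.wmh_mask <- function(x, ...) {
  cat(sprintf("WMH mask: %d voxels (k = %g, components_removed = %s)\n",
              sum(x$mask), x$provenance$k, x$provenance$components_removed))
  invisible(x)
}

#' Connected-component labeling of a 3D mask
#'
#' Breadth-first labeling with 26- (default) or 6-connectivity.
#'
#' @param mask Logical 3D array.
#' @param connectivity 26 or 6.
#' @return Integer array of the same shape; 0 outside the mask, else the
#'   component id.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  coord <- arrayInd(idx, d)
  vox_id <- array(0L, d)
  vox_id[idx] <- seq_along(idx)
  visited <- logical(length(idx))
  comp <- 0L
  for (s in seq_along(idx)) {
    if (visited[s]) next
    comp <- comp + 1L
    visited[s] <- TRUE
    lab[idx[s]] <- comp
    frontier <- s
    while (length(frontier)) {
      fc <- coord[frontier, , drop = FALSE]
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(o)
        cbind(fc[, 1] + off[o, 1], fc[, 2] + off[o, 2], fc[, 3] + off[o, 3])))
      keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      lin <- nb[, 1] + d[1] * ((nb[, 2] - 1) + d[2] * (nb[, 3] - 1))
      cid <- vox_id[lin]
      cid <- unique(cid[cid > 0L])
      cid <- cid[!visited[cid]]
      if (length(cid)) {
        visited[cid] <- TRUE
        lab[idx[cid]] <- comp
      }
      frontier <- cid
    }
  }
  lab
}

#' Remove mask components predominantly adjacent to CSF
#'
#' Labels the 26-connected components of the mask and deletes every component
#' whose boundary (voxel faces counted on the 6-neighborhood; out-of-grid
#' faces count as boundary) is adjacent to CSF on more than `frac` of its
#' faces. This is the cleanup that removes septum and choroid plexus
#' components from the raw threshold mask.
#'
#' @param wmh_mask A [threshold_mask()] result.
#' @param csf_mask Logical array aligned with the mask.
#' @param frac Removal threshold on the CSF-adjacent boundary fraction
#'   (default 0.5, strict inequality).
#' @return A `wmh_mask` with the offending components removed; idempotent.
#' @export
remove_csf_adjacent_components <- function(wmh_mask, csf_mask, frac = 0.5) {
  stopifnot(inherits(wmh_mask, "wmh_mask"),
            identical(dim(csf_mask), dim(wmh_mask$mask)))
  m <- wmh_mask$mask
  d <- dim(m)
  lab <- label_components(m, connectivity = 26)
  ncomp <- max(lab)
  if (ncomp > 0) {
    off6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    for (cid in seq_len(ncomp)) {
      idx <- which(lab == cid)
      co <- arrayInd(idx, d)
      n_bound <- 0L
      n_csf <- 0L
      for (o in seq_len(6)) {
        nb <- cbind(co[, 1] + off6[o, 1], co[, 2] + off6[o, 2], co[, 3] + off6[o, 3])
        inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        n_bound <- n_bound + sum(!inside)
        if (any(inside)) {
          lin <- nb[inside, 1] + d[1] * ((nb[inside, 2] - 1) + d[2] * (nb[inside, 3] - 1))
          outside_comp <- lab[lin] != cid
          n_bound <- n_bound + sum(outside_comp)
          n_csf <- n_csf + sum(outside_comp & csf_mask[lin])
        }
      }
      if (n_bound > 0 && n_csf / n_bound > frac) m[idx] <- FALSE
    }
  }
  structure(list(mask = m,
                 provenance = list(k = wmh_mask$provenance$k, components_removed = TRUE)),
            class = "wmh_mask")
}

#' One-call WMH segmentation
#'
#' [estimate_stats()], [threshold_mask()] and
#' [remove_csf_adjacent_components()] chained with the default k = 2.5.
#'
#' @param vol An [intensity_volume()].
#' @param k Threshold multiplier.
#' @param frac CSF-adjacency removal threshold.
#' @return A `wmh_mask`.
#' @export
segment_wmh <- function(vol, k = 2.5, frac = 0.5) {
  st <- estimate_stats(vol, k = k)
  remove_csf_adjacent_components(threshold_mask(vol, st), vol$csf_mask, frac = frac)
}
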