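# File output: VTK unstructured grid (.vtu, ASCII XML), Gmsh .msh v4.1 with
# physical groups, NIfTI-1 volumes (via RNifti), and flat CSV marker tables.
# No R VTK/Gmsh bindings exist, so the two ASCII writers are implemented
# directly against the published formats (write-only).

fmt_num <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)

#' Write a mesh (and optional fields) as a VTK unstructured grid
#'
#' ASCII XML .vtu with all tetrahedra followed by the tagged surface
#' triangles. Built-in cell data: `region` (1 = WM, 2 = GM, 3 = SAS,
#' 4 = WMH; 0 for surface triangles) and `surface` (0 for tets, then 1-based
#' index of the surface tag). Additional point/cell data arrays may be given
#' as named lists of vectors or matrices (one row per node / per tet; cell
#' arrays are zero-padded over the surface triangles).
#'
#' @param mesh A [labeled_mesh()].
#' @param file Output path.
#' @param point_data,cell_data Named lists of numeric vectors/matrices.
#' @return Invisibly, the file path.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  N <- nrow(mesh$nodes); M <- nrow(mesh$tets)
  tri_list <- mesh$surfaces
  ntri <- vapply(tri_list, nrow, integer(1))
  C <- M + sum(ntri)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', N, C))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  w('        </DataArray>')
  w('      </Points>')
  conn <- c(as.vector(t(mesh$tets)) - 1L,
            unlist(lapply(tri_list, function(s) as.vector(t(s)) - 1L), use.names = FALSE))
  offs <- cumsum(c(rep(4L, M), rep(3L, sum(ntri))))
  types <- c(rep(10L, M), rep(5L, sum(ntri)))
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(conn, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(offs, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(types, collapse = " "), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      nc <- if (is.null(dim(v))) 1L else ncol(v)
      w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, nc))
      vm <- matrix(as.numeric(as.matrix(v)), nrow = N)
      writeLines(apply(vm, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('      <CellData>')
  region_code <- c(match(mesh$region, REGION_LEVELS),
                   unlist(lapply(seq_along(tri_list), function(q) rep(0L, ntri[q])),
                          use.names = FALSE))
  surface_code <- c(rep(0L, M),
                    unlist(lapply(seq_along(tri_list), function(q) rep(q, ntri[q])),
                           use.names = FALSE))
  w('        <DataArray type="Int32" Name="region" format="ascii">')
  writeLines(paste(region_code, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="surface" format="ascii">')
  writeLines(paste(surface_code, collapse = " "), con)
  w('        </DataArray>')
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    nc <- if (is.null(dim(v))) 1L else ncol(v)
    vm <- matrix(as.numeric(as.matrix(v)), nrow = M)
    vm <- rbind(vm, matrix(0, sum(ntri), nc))
    w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              nm, nc))
    writeLines(apply(vm, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Write a mesh in Gmsh .msh v4.1 ASCII format
#'
#' Physical groups: one 3D group per region label present and one 2D group
#' per tagged surface, named accordingly.
#'
#' @param mesh A [labeled_mesh()].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_msh <- function(mesh, file) {
  regions <- intersect(REGION_LEVELS, unique(mesh$region))
  stags <- names(mesh$surfaces)
  nS <- length(stags); nV <- length(regions)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w(sprintf("%d", nS + nV))
  for (q in seq_len(nS)) w(sprintf('2 %d "%s"', q, stags[q]))
  for (q in seq_len(nV)) w(sprintf('3 %d "%s"', nS + q, regions[q]))
  w("$EndPhysicalNames")
  bb <- apply(mesh$nodes, 2, range)
  bbs <- paste(fmt_num(c(bb[1, ], bb[2, ])), collapse = " ")
  w("$Entities")
  w(sprintf("0 0 %d %d", nS, nV))
  for (q in seq_len(nS)) w(sprintf("%d %s 1 %d 0", q, bbs, q))
  for (q in seq_len(nV)) w(sprintf("%d %s 1 %d 0", q, bbs, nS + q))
  w("$EndEntities")
  N <- nrow(mesh$nodes)
  w("$Nodes")
  # single block: all nodes attached to the first volume entity
  w(sprintf("1 %d 1 %d", N, N))
  w(sprintf("3 %d 0 %d", if (nV) 1L else 1L, N))
  writeLines(as.character(seq_len(N)), con)
  writeLines(apply(mesh$nodes, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  w("$EndNodes")
  blocks <- list()
  eid <- 0L
  for (q in seq_len(nS)) {
    s <- mesh$surfaces[[stags[q]]]
    lines <- sprintf("%d %d %d %d", eid + seq_len(nrow(s)), s[, 1], s[, 2], s[, 3])
    eid <- eid + nrow(s)
    blocks[[length(blocks) + 1L]] <- c(sprintf("2 %d 2 %d", q, nrow(s)), lines)
  }
  for (q in seq_len(nV)) {
    sel <- which(mesh$region == regions[q])
    t4 <- mesh$tets[sel, , drop = FALSE]
    lines <- sprintf("%d %d %d %d %d", eid + seq_along(sel),
                     t4[, 1], t4[, 2], t4[, 3], t4[, 4])
    eid <- eid + length(sel)
    blocks[[length(blocks) + 1L]] <- c(sprintf("3 %d 4 %d", q, length(sel)), lines)
  }
  w("$Elements")
  w(sprintf("%d %d 1 %d", length(blocks), eid, eid))
  for (b in blocks) writeLines(b, con)
  w("$EndElements")
  invisible(file)
}

#' Write an intensity volume (and its masks) as NIfTI-1
#'
#' The scalar volume is written as float32 with the voxel spacing in the
#' header; the brain and CSF masks are written as uint8 alongside (suffixes
#' `_brainmask`, `_csfmask`) when `masks = TRUE`.
#'
#' @param vol An [intensity_volume()].
#' @param file Output path (`.nii` or `.nii.gz`).
#' @param masks Also write the mask volumes.
#' @return Invisibly, the main file path.
#' @export
write_volume_nifti <- function(vol, file, masks = TRUE) {
  im <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(im) <- vol$spacing
  RNifti::writeNifti(im, file, datatype = "float")
  if (masks) {
    base <- sub("\\.nii(\\.gz)?$", "", file)
    ext <- if (grepl("\\.nii\\.gz$", file)) ".nii.gz" else ".nii"
    for (mk in c("brain_mask", "csf_mask")) {
      mi <- RNifti::asNifti(array(as.integer(vol[[mk]]), dim(vol[[mk]])))
      RNifti::pixdim(mi) <- vol$spacing
      RNifti::writeNifti(mi, paste0(base, "_", sub("_mask", "mask", mk), ext),
                         datatype = "uint8")
    }
  }
  invisible(file)
}

#' Read a NIfTI volume into an intensity_volume
#'
#' @param file Scalar NIfTI path.
#' @param brain_mask_file,csf_mask_file Optional mask NIfTI paths (nonzero =
#'   TRUE); the brain mask defaults to all voxels.
#' @return An [intensity_volume()].
#' @export
read_volume_nifti <- function(file, brain_mask_file = NULL, csf_mask_file = NULL) {
  im <- RNifti::readNifti(file)
  arr <- array(as.numeric(im), dim(im))
  sp <- RNifti::pixdim(im)[1:3]
  bm <- if (is.null(brain_mask_file)) NULL else {
    b <- RNifti::readNifti(brain_mask_file); array(as.numeric(b) != 0, dim(b))
  }
  cm <- if (is.null(csf_mask_file)) NULL else {
    b <- RNifti::readNifti(csf_mask_file); array(as.numeric(b) != 0, dim(b))
  }
  intensity_volume(arr, spacing = sp, brain_mask = bm, csf_mask = cm)
}

#' Export wall frames and the Laplace field for inspection
#'
#' Writes a .vtu with the temperature field as point data and, over the tets,
#' the frame vectors `n`, `v1`, `v2` (zero on non-wall elements).
#'
#' @param mesh A [labeled_mesh()].
#' @param field A [solve_laplace()] result.
#' @param frames A [compute_wall_frames()] result.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_frames_vtu <- function(mesh, field, frames, file) {
  M <- nrow(mesh$tets)
  n <- v1 <- v2 <- matrix(0, M, 3)
  n[frames$tet, ] <- frames$n
  v1[frames$tet, ] <- frames$v1
  v2[frames$tet, ] <- frames$v2
  write_vtu(mesh, file, point_data = list(T = field$nodal_T),
            cell_data = list(n = n, v1 = v1, v2 = v2))
}
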