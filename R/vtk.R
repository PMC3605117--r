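# ---------------------------------------------------------------------------
# Legacy VTK (ASCII) export/import for unstructured meshes. Elements and
# tagged boundary facets are written as one mixed-cell block; integer cell
# fields `compartment` (0 on facets) and `boundary` (0 on elements) carry
# the labels. Scalar/vector point data may be attached.
# ---------------------------------------------------------------------------

vtk_cell_type <- function(nvert) switch(as.character(nvert),
  "1" = 1L,   # vertex
  "2" = 3L,   # line
  "3" = 5L,   # triangle
  "4" = 10L,  # tetra
  stop("unsupported cell size ", nvert))

#' Write a mesh (and optional nodal fields) as legacy ASCII VTK
#'
#' @param mesh a `uw_mesh`
#' @param file output path (conventionally `.vtk`)
#' @param point_data named list of numeric vectors (length n_nodes) or
#'   matrices (n_nodes x 3) written as point scalars/vectors
#' @return the file path, invisibly
#' @export
write_vtk <- function(mesh, file, point_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  nd <- mesh$nodes
  if (ncol(nd) < 3L) nd <- cbind(nd, matrix(0, nrow(nd), 3L - ncol(nd)))
  writeLines(c("# vtk DataFile Version 3.0",
               "uterowave unstructured mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(nd)), con)
  writeLines(paste(format(nd[, 1], digits = 17, scientific = TRUE, trim = TRUE),
                   format(nd[, 2], digits = 17, scientific = TRUE, trim = TRUE),
                   format(nd[, 3], digits = 17, scientific = TRUE, trim = TRUE)),
             con)
  cells <- list(mesh$elems)
  types <- rep(vtk_cell_type(ncol(mesh$elems)), nrow(mesh$elems))
  comp <- mesh$elem_label
  bnd <- rep(0L, nrow(mesh$elems))
  if (!is.null(mesh$facets) && nrow(mesh$facets) > 0L) {
    cells[[2]] <- mesh$facets
    types <- c(types, rep(vtk_cell_type(ncol(mesh$facets)), nrow(mesh$facets)))
    comp <- c(comp, rep(0L, nrow(mesh$facets)))
    bnd <- c(bnd, mesh$facet_label)
  }
  ncell <- length(types)
  sizes <- vapply(cells, ncol, 1L)
  total <- sum(vapply(cells, function(m) nrow(m) * (ncol(m) + 1L), 1L))
  writeLines(sprintf("CELLS %d %d", ncell, total), con)
  for (blk in cells) {
    writeLines(apply(cbind(ncol(blk), blk - 1L), 1, paste, collapse = " "), con)
  }
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(as.character(types), con)
  writeLines(sprintf("CELL_DATA %d", ncell), con)
  writeLines(c("SCALARS compartment int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(comp), con)
  writeLines(c("SCALARS boundary int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(bnd), con)
  if (length(point_data) > 0L) {
    writeLines(sprintf("POINT_DATA %d", nrow(nd)), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.null(dim(v))) {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(v, digits = 17, scientific = TRUE, trim = TRUE), con)
      } else {
        v3 <- cbind(v, matrix(0, nrow(v), max(0L, 3L - ncol(v))))
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(paste(
          format(v3[, 1], digits = 17, scientific = TRUE, trim = TRUE),
          format(v3[, 2], digits = 17, scientific = TRUE, trim = TRUE),
          format(v3[, 3], digits = 17, scientific = TRUE, trim = TRUE)), con)
      }
    }
  }
  invisible(file)
}

#' Read a mesh written by [write_vtk()]
#'
#' Cells with `dim + 1` vertices are taken as elements, cells with `dim`
#' vertices as boundary facets; the `compartment` and `boundary` cell fields
#' restore the labels.
#'
#' @param file path to a legacy ASCII VTK file
#' @return a `uw_mesh`
#' @export
read_vtk <- function(file) {
  ln <- readLines(file)
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(ln[(ip + 1):(ip + np)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  ic <- grep("^CELLS", ln)[1]
  nc <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  cl <- lapply(ln[(ic + 1):(ic + nc)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]]))
  sizes <- vapply(cl, function(x) x[1], 1L)
  dim_ <- max(sizes) - 1L
  icd <- grep("^SCALARS compartment", ln)[1]
  comp <- as.integer(ln[(icd + 2):(icd + 1 + nc)])
  ibd <- grep("^SCALARS boundary", ln)[1]
  bnd <- as.integer(ln[(ibd + 2):(ibd + 1 + nc)])
  is_el <- sizes == dim_ + 1L
  elems <- do.call(rbind, lapply(cl[is_el], function(x) x[-1] + 1L))
  fc <- NULL; fl <- integer(0)
  if (any(!is_el)) {
    fc <- do.call(rbind, lapply(cl[!is_el], function(x) x[-1] + 1L))
    fl <- bnd[!is_el]
  }
  # drop padded zero coordinates for low-dimensional meshes
  nodes <- pts[, seq_len(dim_), drop = FALSE]
  new_mesh(nodes, elems, comp[is_el], fc, fl, dim_)
}
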