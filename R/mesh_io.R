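# Mesh and landmark exchange: Gmsh MSH v2.2 (ASCII), VTU (XML unstructured
# grid, ASCII) and landmark JSON. Region labels map to physical tags in MSH
# and to a cell-data array in VTU.

.region_codes <- c(skull_base = 1L, maxilla_mobile = 2L, cartilage = 3L,
                   soft_tissue = 4L)

#' Write a labelled tetrahedral mesh as Gmsh MSH v2.2
#'
#' Regions are encoded as physical/elementary tags (1 skull_base,
#' 2 maxilla_mobile, 3 cartilage, 4 soft_tissue).
#'
#' @param mesh a `labeled_tet_mesh`.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); nt <- nrow(mesh$tets)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nn)), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(nn),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nt)), con)
  tag <- .region_codes[mesh$region]
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nt), tag, tag,
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH v2.2 tetrahedral mesh
#'
#' Only 4-node tetrahedra (element type 4) are read; the first tag is mapped
#' back to the region labels written by [write_msh()].
#'
#' @param path MSH file path.
#' @return a `labeled_tet_mesh` (without phantom node sets or geometry).
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stopf("MSH file lacks section %s", name)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(sec("MeshFormat")[1], " ")[[1]]
  if (fmt[1] != "2.2") stopf("unsupported MSH version %s (expect 2.2)", fmt[1])
  nl <- sec("Nodes")
  nn <- as.integer(nl[1])
  nd <- matrix(as.numeric(unlist(strsplit(nl[-1], " +"))), ncol = 4L, byrow = TRUE)
  nodes <- nd[order(nd[, 1]), 2:4, drop = FALSE]
  el <- sec("Elements")[-1]
  parts <- strsplit(el, " +")
  keep <- vapply(parts, function(p) as.integer(p[2]) == 4L, logical(1))
  parts <- parts[keep]
  if (length(parts) == 0L) stopf("no tetrahedra in MSH file")
  mat <- t(vapply(parts, function(p) {
    ntag <- as.integer(p[3])
    as.integer(c(p[4], p[(4L + ntag):(7L + ntag)]))
  }, integer(5)))
  region <- names(.region_codes)[match(mat[, 1], .region_codes)]
  region[is.na(region)] <- "soft_tissue"
  structure(list(nodes = nodes, tets = mat[, 2:5, drop = FALSE], region = region,
                 cell = NULL, node_sets = list(), geometry = NULL, seed = NA_integer_),
            class = "labeled_tet_mesh")
}

#' Write a mesh (optionally with point data) as VTU
#'
#' ASCII XML VTK unstructured grid with the region id as cell data and any
#' number of 3-component point-data arrays (e.g. a displacement field).
#'
#' @param mesh a `labeled_tet_mesh`.
#' @param path output file path.
#' @param point_data named list of numeric data: length-n vectors or n-by-3
#'   matrices (n = number of nodes).
#' @return invisibly `path`.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  nn <- nrow(mesh$nodes); nt <- nrow(mesh$tets)
  num <- function(x) paste(format(x, digits = 10, trim = TRUE, scientific = FALSE),
                           collapse = " ")
  out <- c('<?xml version="1.0"?>',
           '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
           '<UnstructuredGrid>',
           sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, nt),
           '<Points>',
           '<DataArray type="Float64" NumberOfComponents="3" format="ascii">',
           num(t(mesh$nodes)),
           '</DataArray>', '</Points>', '<Cells>',
           '<DataArray type="Int32" Name="connectivity" format="ascii">',
           paste(as.vector(t(mesh$tets)) - 1L, collapse = " "),
           '</DataArray>',
           '<DataArray type="Int32" Name="offsets" format="ascii">',
           paste(seq_len(nt) * 4L, collapse = " "),
           '</DataArray>',
           '<DataArray type="UInt8" Name="types" format="ascii">',
           paste(rep(10L, nt), collapse = " "),
           '</DataArray>', '</Cells>',
           '<CellData Scalars="region">',
           '<DataArray type="Int32" Name="region" format="ascii">',
           paste(.region_codes[mesh$region], collapse = " "),
           '</DataArray>', '</CellData>')
  if (length(point_data)) {
    out <- c(out, '<PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      if ((is.matrix(v) && nrow(v) != nn) || (!is.matrix(v) && length(v) != nn))
        stopf("point_data '%s' does not match the node count", nm)
      out <- c(out,
               sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                       nm, nc),
               num(if (is.matrix(v)) t(v) else v),
               '</DataArray>')
    }
    out <- c(out, '</PointData>')
  }
  out <- c(out, '</Piece>', '</UnstructuredGrid>', '</VTKFile>')
  writeLines(out, path)
  invisible(path)
}

#' Write or read a landmark set as JSON
#'
#' Serialised as `{name: node_index}` (1-based node indices).
#'
#' @param landmarks a `landmark_set`.
#' @param path file path.
#' @return `write_landmarks_json()` returns `path` invisibly;
#'   `read_landmarks_json()` returns a `landmark_set` (coordinates attached if
#'   `mesh` is given).
#' @export
write_landmarks_json <- function(landmarks, path) {
  jsonlite::write_json(as.list(unclass(landmarks)), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @param mesh optional `labeled_tet_mesh` used to attach coordinates.
#' @export
read_landmarks_json <- function(path, mesh = NULL) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- unlist(lst)
  co <- if (!is.null(mesh)) {
    m <- mesh$nodes[idx, , drop = FALSE]
    dimnames(m) <- list(names(idx), c("x", "y", "z"))
    m
  } else NULL
  structure(as.integer(idx), names = names(idx), coords = co, class = "landmark_set")
}

#' Write landmark displacement time histories as CSV
#'
#' One row per stored time with columns `time, N, UL, LL, RC, LC` (anterior
#' displacement, mm).
#'
#' @param field a `displacement_field`.
#' @param landmarks a `landmark_set`.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_landmark_history <- function(field, landmarks, path) {
  idx <- as.integer(unclass(landmarks))
  ydofs <- 3L * (idx - 1L) + 2L
  df <- data.frame(time = field$times, t(field$U[ydofs, , drop = FALSE]))
  names(df) <- c("time", names(landmarks))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
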