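#' Single-region rectangular block mesh for solver verification
#'
#' Structured tetrahedral block (6 tets per hexahedral cell) with one region
#' label, used for verification studies against closed-form solutions (e.g.
#' uniaxial extension) rather than for phantom modelling.
#'
#' @param lx,ly,lz block dimensions (mm); the block spans `[0, lx]` etc.
#' @param edge target element edge length (mm).
#' @param region region label applied to every tetrahedron.
#' @return a `labeled_tet_mesh` with node sets `<region>.{x,y,z}_{min,max}`.
#' @export
block_mesh <- function(lx = 10, ly = 10, lz = 10, edge = 2.5, region = "soft_tissue") {
  if (any(c(lx, ly, lz, edge) <= 0)) stopf("block dimensions and edge must be positive")
  nx <- max(1L, round(lx / edge)); ny <- max(1L, round(ly / edge)); nz <- max(1L, round(lz / edge))
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  zs <- seq(0, lz, length.out = nz + 1L)
  node_id <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz),
                       KEEP.OUT.ATTRS = FALSE)
  i <- cells$i; j <- cells$j; k <- cells$k
  corners <- cbind(node_id(i,      j,      k),
                   node_id(i + 1L, j,      k),
                   node_id(i + 1L, j + 1L, k),
                   node_id(i,      j + 1L, k),
                   node_id(i,      j,      k + 1L),
                   node_id(i + 1L, j,      k + 1L),
                   node_id(i + 1L, j + 1L, k + 1L),
                   node_id(i,      j + 1L, k + 1L))
  tets <- do.call(rbind, lapply(seq_len(6L), function(t) corners[, .hex_tets[t, ], drop = FALSE]))
  cell <- rep(seq_len(nrow(cells)), times = 6L)
  vol <- .tet_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]
  tol <- 1e-8 * max(lx, ly, lz)
  on_plane <- function(col, val) which(abs(nodes[, col] - val) < tol)
  sets <- list(on_plane(1, 0), on_plane(1, lx), on_plane(2, 0), on_plane(2, ly),
               on_plane(3, 0), on_plane(3, lz))
  names(sets) <- paste0(region, c(".x_min", ".x_max", ".y_min", ".y_max", ".z_min", ".z_max"))
  structure(list(nodes = nodes, tets = tets,
                 region = rep(region, nrow(tets)), cell = cell,
                 node_sets = sets,
                 geometry = list(lx = lx, ly = ly, lz = lz, edge = edge),
                 seed = 0L),
            class = "labeled_tet_mesh")
}
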