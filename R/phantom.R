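#' Geometry parameters for the synthetic midface phantom
#'
#' The phantom is a rectangular layered block that preserves the mechanical
#' structure of the midface after a Le Fort I osteotomy: a stiff posterior bone
#' plate split by an osteotomy gap into a fixed skull base (above the cut) and a
#' mobile maxillary segment (below the cut), a cartilage inclusion buried in the
#' soft tissue under the nose landmark, and a near-incompressible soft-tissue
#' layer covering the bone and filling the sub-maxillary (lip/chin) region.
#'
#' Coordinates: x lateral (midline at x = 0), y anterior (the advancement
#' direction), z superior. All lengths in mm.
#'
#' @param width lateral extent (mm); the block spans x in `[-width/2, width/2]`.
#' @param height superior extent (mm); z in `[0, height]`.
#' @param bone_depth anterior thickness of the bone plate (mm), y in
#'   `[0, bone_depth]`.
#' @param soft_depth thickness of the soft-tissue layer anterior to the bone
#'   (mm); the skin surface is at y = `bone_depth + soft_depth`.
#' @param bone_zmin inferior limit of the bone plate (mm); below it the full
#'   depth is soft tissue (lips/chin over no bone).
#' @param cut_z height of the osteotomy plane (mm); bone below the cut (down to
#'   `bone_zmin`) is the mobile maxillary segment, bone above the gap is skull
#'   base.
#' @param gap height of the osteotomy gap (mm); at least one element layer is
#'   always left empty so the two bone segments share no nodes.
#' @param cartilage list with `half_width`, `z` (2-vector) and `depth` (mm)
#'   locating the cartilage inclusion inside the soft-tissue layer beneath the
#'   nose landmark; `depth` must be strictly less than `soft_depth`. With the
#'   defaults the inclusion is rooted on the mobile segment below the cut and
#'   bridges up behind the nose landmark, like the nasal cartilage riding on
#'   the maxilla.
#' @param aperture list with `half_width` and `z_top` (mm): a window left
#'   unmeshed in the skull base above the osteotomy, emulating the piriform
#'   aperture / nasal cavity — there is no fixed bone directly behind the
#'   nose.
#' @param landmarks named list of `(x, z)` positions on the skin surface for
#'   the five output probe points N (pronasale), UL (labrale superius),
#'   LL (labrale inferius), RC and LC (right/left cheek).
#' @param edge target element edge length (mm); the mesh density parameter.
#' @return an object of class `phantom_geometry` (a validated list).
#' @export
phantom_geometry <- function(width = 80, height = 80,
                             bone_depth = 10, soft_depth = 15,
                             bone_zmin = 10, cut_z = 40, gap = 5,
                             cartilage = list(half_width = 15, z = c(35, 60), depth = 10),
                             aperture = list(half_width = 30, z_top = 65),
                             landmarks = list(N = c(0, 50), UL = c(0, 25), LL = c(0, 15),
                                              RC = c(25, 50), LC = c(-25, 50)),
                             edge = 5) {
  g <- list(width = width, height = height, bone_depth = bone_depth,
            soft_depth = soft_depth, bone_zmin = bone_zmin, cut_z = cut_z,
            gap = gap, cartilage = cartilage, aperture = aperture,
            landmarks = landmarks, edge = edge)
  dims <- c(width = width, height = height, bone_depth = bone_depth,
            soft_depth = soft_depth, gap = gap, edge = edge)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stopf("degenerate phantom geometry: all dimensions must be positive and finite")
  if (bone_zmin <= 0 || bone_zmin >= cut_z)
    stopf("osteotomy plane must lie above the inferior bone limit (bone_zmin < cut_z)")
  if (cut_z + gap >= height)
    stopf("osteotomy plane (plus gap) must lie inside the bone plate (cut_z + gap < height)")
  if (cartilage$depth >= soft_depth)
    stopf("cartilage depth must be strictly less than soft_depth (inclusion inside the layer)")
  if (cartilage$half_width <= 0 || diff(cartilage$z) <= 0)
    stopf("degenerate cartilage box")
  need <- c("N", "UL", "LL", "RC", "LC")
  if (!all(need %in% names(landmarks)))
    stopf("landmarks must include %s", paste(need, collapse = ", "))
  for (nm in need) {
    lz <- landmarks[[nm]]
    if (length(lz) != 2 || abs(lz[1]) > width / 2 || lz[2] < 0 || lz[2] > height)
      stopf("landmark %s lies outside the phantom", nm)
  }
  class(g) <- "phantom_geometry"
  g
}

# 6-tetrahedra decomposition of a hexahedral cell, all sharing diagonal v1-v7
# (corners in the order (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),
# (1,1,1),(0,1,1)); a consistent decomposition across cells so shared faces
# are conforming.
.hex_tets <- matrix(c(1, 2, 3, 7,
                      1, 3, 4, 7,
                      1, 4, 8, 7,
                      1, 8, 5, 7,
                      1, 5, 6, 7,
                      1, 6, 2, 7), ncol = 4, byrow = TRUE)

.tet_volumes <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c3 <- nodes[tets[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
   a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
   a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Build the synthetic layered midface phantom
#'
#' Meshes the block described by a [phantom_geometry()] by structured
#' subdivision into hexahedral cells, each split into 6 linear tetrahedra.
#' Cells are assigned one region each (`skull_base`, `maxilla_mobile`,
#' `cartilage`, `soft_tissue`) by their centroid; the osteotomy gap row is left
#' unmeshed so the two bone segments share no nodes, while both remain bonded
#' to the soft tissue through shared interface nodes. The five landmarks are
#' snapped to the nearest skin-surface nodes.
#'
#' @param geometry a [phantom_geometry()].
#' @param seed integer; recorded with the mesh. The structured mesher is fully
#'   deterministic, the seed takes part in cache keys downstream.
#' @return a list with components `mesh` (class `labeled_tet_mesh`: `nodes`
#'   n-by-3 matrix, `tets` m-by-4 integer matrix, `region` character per
#'   tetrahedron, `node_sets` named list of node index vectors, `geometry`,
#'   `seed`) and `landmarks` (class `landmark_set`: named integer node indices
#'   with a `coords` attribute).
#' @export
build_phantom <- function(geometry = phantom_geometry(), seed = 1L) {
  if (!inherits(geometry, "phantom_geometry")) geometry <- do.call(phantom_geometry, geometry)
  g <- geometry
  depth_total <- g$bone_depth + g$soft_depth
  nx <- 2L * max(1L, round(g$width / (2 * g$edge)))
  ny <- max(2L, round(depth_total / g$edge))
  nz <- max(4L, round(g$height / g$edge))
  xs <- seq(-g$width / 2, g$width / 2, length.out = nx + 1L)
  ys <- seq(0, depth_total, length.out = ny + 1L)
  zs <- seq(0, g$height, length.out = nz + 1L)
  dz <- g$height / nz

  # node grid, index (i,j,k) -> linear
  nn <- (nx + 1L) * (ny + 1L) * (nz + 1L)
  node_id <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L) # i in 1..nx+1
  grid <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  nodes <- as.matrix(grid)

  # cell centroids and region classification
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz),
                       KEEP.OUT.ATTRS = FALSE)
  cx <- (xs[cells$i] + xs[cells$i + 1L]) / 2
  cy <- (ys[cells$j] + ys[cells$j + 1L]) / 2
  cz <- (zs[cells$k] + zs[cells$k + 1L]) / 2
  gap_hi <- g$cut_z + max(g$gap, dz) # at least one empty layer regardless of density
  region <- rep("soft_tissue", nrow(cells))
  in_bone_col <- cy < g$bone_depth
  region[in_bone_col & cz < g$bone_zmin] <- "soft_tissue"
  region[in_bone_col & cz >= g$bone_zmin & cz < g$cut_z] <- "maxilla_mobile"
  region[in_bone_col & cz >= g$cut_z & cz < gap_hi] <- NA # osteotomy gap: unmeshed
  region[in_bone_col & cz >= gap_hi] <- "skull_base"
  if (!is.null(g$aperture)) {
    # piriform aperture: no fixed bone directly behind the nose
    region[in_bone_col & cz >= gap_hi & cz < g$aperture$z_top &
             abs(cx) <= g$aperture$half_width] <- NA
  }
  cb <- g$cartilage
  in_cart <- !in_bone_col & abs(cx) <= cb$half_width &
    cz >= cb$z[1] & cz <= cb$z[2] &
    cy >= g$bone_depth & cy < g$bone_depth + cb$depth
  region[in_cart] <- "cartilage"

  keep <- !is.na(region)
  cells <- cells[keep, , drop = FALSE]
  region <- region[keep]
  if (!any(region == "maxilla_mobile") || !any(region == "skull_base"))
    stopf("mesh density too coarse: osteotomy does not separate two bone segments")
  if (!any(region == "cartilage"))
    stopf("mesh density too coarse: cartilage inclusion not resolved")

  # hex corner node ids (cell-local corner order as in .hex_tets)
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
  tet_region <- rep(region, times = 6L)
  tet_cell <- rep(seq_len(nrow(cells)), times = 6L) # parent hex of each tet

  # fix orientation (positive volumes)
  vol <- .tet_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]
  vol <- abs(vol)
  if (any(vol <= 0)) stopf("degenerate (zero-volume) tetrahedra in phantom mesh")

  # drop unreferenced nodes, renumber
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nn); remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)
  nodes <- nodes[used, , drop = FALSE]
  if (nrow(nodes) < 100L)
    stopf("mesh density yields %d nodes (< 100); refine `edge`", nrow(nodes))

  mesh <- structure(list(nodes = nodes, tets = tets, region = tet_region,
                         cell = tet_cell, node_sets = list(), geometry = g,
                         seed = as.integer(seed)),
                    class = "labeled_tet_mesh")
  mesh$node_sets <- .phantom_node_sets(mesh)
  landmarks <- .place_landmarks(mesh)
  list(mesh = mesh, landmarks = landmarks)
}

.region_nodes <- function(mesh, region) {
  sort(unique(as.vector(mesh$tets[mesh$region == region, , drop = FALSE])))
}

# boundary faces (faces appearing exactly once) of a sub-mesh
.boundary_nodes <- function(tets) {
  faces <- rbind(tets[, c(1L, 2L, 3L)], tets[, c(1L, 2L, 4L)],
                 tets[, c(1L, 3L, 4L)], tets[, c(2L, 3L, 4L)])
  faces <- t(apply(faces, 1L, sort))
  key <- paste(faces[, 1L], faces[, 2L], faces[, 3L])
  once <- names(which(table(key) == 1L))
  sort(unique(as.vector(faces[key %in% once, , drop = FALSE])))
}

.phantom_node_sets <- function(mesh) {
  g <- mesh$geometry
  tol <- 1e-8 * max(g$width, g$height)
  xyz <- mesh$nodes
  ymin <- min(xyz[, 2]); ymax <- max(xyz[, 2])
  zmin <- min(xyz[, 3]); zmax <- max(xyz[, 3])
  sets <- list()
  for (r in c("skull_base", "maxilla_mobile", "cartilage", "soft_tissue")) {
    rn <- .region_nodes(mesh, r)
    sets[[paste0(r, ".y_min")]] <- rn[abs(xyz[rn, 2] - ymin) < tol]
    sets[[paste0(r, ".y_max")]] <- rn[abs(xyz[rn, 2] - ymax) < tol]
    sets[[paste0(r, ".z_min")]] <- rn[abs(xyz[rn, 3] - zmin) < tol]
    sets[[paste0(r, ".z_max")]] <- rn[abs(xyz[rn, 3] - zmax) < tol]
  }
  sets[["maxilla_mobile.surface"]] <-
    .boundary_nodes(mesh$tets[mesh$region == "maxilla_mobile", , drop = FALSE])
  sets
}

.place_landmarks <- function(mesh) {
  g <- mesh$geometry
  skin <- mesh$node_sets[["soft_tissue.y_max"]]
  if (length(skin) == 0L) stopf("phantom has no skin surface nodes")
  xyz <- mesh$nodes
  idx <- vapply(c("N", "UL", "LL", "RC", "LC"), function(nm) {
    p <- g$landmarks[[nm]]
    d2 <- (xyz[skin, 1] - p[1])^2 + (xyz[skin, 3] - p[2])^2
    # mirror-symmetric tie-break: prefer the more lateral, then higher node
    tied <- which(d2 <= min(d2) + 1e-9)
    tied <- tied[order(-abs(xyz[skin[tied], 1]), -xyz[skin[tied], 3])]
    skin[tied[1L]]
  }, integer(1))
  if (anyDuplicated(idx)) stopf("landmarks collapse onto a shared node; refine `edge`")
  co <- xyz[idx, , drop = FALSE]
  dimnames(co) <- list(names(idx), c("x", "y", "z"))
  structure(idx, coords = co, class = "landmark_set")
}

#' Check the phantom mesh invariants
#'
#' Verifies region labelling, positive volumes, osteotomy separation (skull
#' base and mobile segment share no nodes while both share nodes with the soft
#' tissue), the cartilage inclusion position, and landmark placement on the
#' skin surface with RC/LC mirror-symmetric about the midline.
#'
#' @param mesh a `labeled_tet_mesh`.
#' @param landmarks a `landmark_set`.
#' @return invisibly `TRUE`; otherwise an error describing the violated
#'   invariant.
#' @export
validate_phantom <- function(mesh, landmarks) {
  regions <- c("skull_base", "maxilla_mobile", "cartilage", "soft_tissue")
  if (!all(mesh$region %in% regions)) stopf("unknown region label")
  if (any(.tet_volumes(mesh$nodes, mesh$tets) <= 0)) stopf("non-positive tet volume")
  base_n <- .region_nodes(mesh, "skull_base")
  mob_n <- .region_nodes(mesh, "maxilla_mobile")
  soft_n <- .region_nodes(mesh, "soft_tissue")
  if (length(intersect(base_n, mob_n)) > 0L)
    stopf("osteotomy violated: skull base and mobile segment share nodes")
  if (length(intersect(base_n, soft_n)) == 0L || length(intersect(mob_n, soft_n)) == 0L)
    stopf("bone segments are not bonded to the soft tissue")
  # cartilage inside the soft-tissue layer, beneath landmark N
  g <- mesh$geometry
  cart_tets <- mesh$tets[mesh$region == "cartilage", , drop = FALSE]
  cart_xyz <- mesh$nodes[unique(as.vector(cart_tets)), , drop = FALSE]
  ys <- sort(unique(mesh$nodes[, 2]))
  dy <- min(diff(ys)) # cells are classified by centroid: allow half a cell
  if (any(cart_xyz[, 2] < g$bone_depth - dy / 2 - 1e-9) ||
      any(cart_xyz[, 2] > g$bone_depth + g$soft_depth + 1e-9))
    stopf("cartilage extends outside the soft-tissue layer")
  n_xy <- attr(landmarks, "coords")["N", ]
  if (!(n_xy[1] >= min(cart_xyz[, 1]) && n_xy[1] <= max(cart_xyz[, 1]) &&
        n_xy[3] >= min(cart_xyz[, 3]) && n_xy[3] <= max(cart_xyz[, 3])))
    stopf("landmark N is not over the cartilage inclusion")
  # landmarks: distinct soft-tissue skin nodes; RC/LC mirror symmetric
  skin <- mesh$node_sets[["soft_tissue.y_max"]]
  if (anyDuplicated(unclass(landmarks))) stopf("duplicate landmark nodes")
  if (!all(unclass(landmarks) %in% skin)) stopf("landmark off the skin surface")
  co <- attr(landmarks, "coords")
  if (abs(co["RC", 1] + co["LC", 1]) > 1e-8 || abs(co["RC", 3] - co["LC", 3]) > 1e-8)
    stopf("RC/LC are not mirror-symmetric about the midline")
  invisible(TRUE)
}

#' @export
print.labeled_tet_mesh <- function(x, ...) {
  cat("labeled_tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tetrahedra\n")
  print(table(x$region))
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  co <- attr(x, "coords")
  df <- data.frame(node = unclass(x), x = co[, 1], y = co[, 2], z = co[, 3])
  print(df)
  invisible(x)
}

#' Synthesise ground-truth postoperative landmark displacements
#'
#' Stands in for postoperative imaging: runs the forward viscoelastic solve at
#' a hidden "true" input vector and adds zero-mean Gaussian measurement noise
#' to the five landmark displacements.
#'
#' @param mesh,landmarks phantom mesh and landmark set from [build_phantom()].
#' @param true_inputs an [input_vector()] of the hidden true material
#'   properties and achieved advancement.
#' @param noise_sd landmark identification noise (mm, standard deviation).
#' @param seed integer seed for the noise draw (the solve is deterministic).
#' @param bc,prony,time_grid,system optional overrides forwarded to
#'   [solve_viscoelastic()].
#' @return named numeric of length 5 (N, UL, LL, RC, LC): anterior (y)
#'   displacement in mm.
#' @export
synthesize_truth <- function(mesh, landmarks, true_inputs, noise_sd = 0.2, seed = 1L,
                             bc = NULL, prony = prony_series(), time_grid = NULL,
                             system = NULL) {
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  bc <- bc %||% default_boundary_spec(mesh)
  time_grid <- time_grid %||% make_time_grid()
  field <- solve_viscoelastic(mesh, bc, true_inputs, prony = prony,
                              time_grid = time_grid, system = system)
  y <- extract_landmarks(field, landmarks)
  if (noise_sd > 0) y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  y
}

#' Load the packaged eight-patient cohort table
#'
#' Plain-text fixture with patient id, age, sex, the three imaging/surgery
#' time intervals (days) and the planned maxillary advancement (mm) for the
#' eight-subject cohort the pipeline's synthetic subjects mirror.
#'
#' @return a data.frame with 8 rows.
#' @export
load_cohort_table <- function() {
  f <- system.file("extdata", "cohort_table1.csv", package = "facefem", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Summary statistic of a cohort-table column
#'
#' @param table data.frame from [load_cohort_table()].
#' @param column column name.
#' @param statistic `"mean"` or `"sd"` (sample, n-1 denominator).
#' @param rounding `"none"`, `"integer"` (half away from zero) or `"1dp"`.
#' @return a single number.
#' @export
summarize_column <- function(table, column,
                             statistic = c("mean", "sd"),
                             rounding = c("none", "integer", "1dp")) {
  statistic <- match.arg(statistic)
  rounding <- match.arg(rounding)
  if (!column %in% names(table)) stopf("unknown column '%s'", column)
  x <- table[[column]]
  if (!is.numeric(x)) stopf("column '%s' is not numeric", column)
  v <- switch(statistic, mean = mean(x), sd = stats::sd(x))
  switch(rounding,
         none = v,
         integer = round_half_away(v, 0),
         `1dp` = round_half_away(v, 1))
}
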