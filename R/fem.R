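#' Prony series for normalised shear relaxation
#'
#' Two-term default `g = (0.325, 0.3)`, `tau = (1, 6)` s: 62.5% total
#' long-time relaxation at unit scale factor.
#'
#' @param g relaxation weights (dimensionless, all positive, sum < 1).
#' @param tau characteristic times (s, all positive).
#' @return object of class `prony_series`.
#' @export
prony_series <- function(g = c(0.325, 0.3), tau = c(1, 6)) {
  if (length(g) != length(tau) || length(g) < 1L)
    stopf("g and tau must be non-empty and of equal length")
  if (any(g <= 0) || any(tau <= 0)) stopf("Prony weights and times must be positive")
  if (sum(g) >= 1) stopf("sum of Prony weights must be < 1 (long-time modulus positive)")
  structure(list(g = g, tau = tau, n = length(g)), class = "prony_series")
}

#' Normalised shear relaxation modulus
#'
#' `G(t) = 1 - scale * sum_i g_i (1 - exp(-t / tau_i))`: monotone
#' non-increasing from 1 at `t = 0` to the long-time plateau
#' `1 - scale * sum(g)`.
#'
#' @param t time (s), vectorised; must be non-negative.
#' @param prony a [prony_series()].
#' @param scale viscoelastic scale factor applied to the weights; requires
#'   `scale * sum(g) < 1`.
#' @return normalised modulus, same length as `t`.
#' @export
shear_relaxation <- function(t, prony = prony_series(), scale = 1) {
  if (any(t < 0)) stopf("negative time in shear_relaxation")
  if (scale * sum(prony$g) >= 1)
    stopf("scale * sum(g) must be < 1 (long-time modulus positive)")
  rel <- vapply(t, function(tt) sum(scale * prony$g * (1 - exp(-tt / prony$tau))),
                numeric(1))
  1 - rel
}

#' One realisation of the uncertain model inputs
#'
#' @param E_bone,nu_bone bone Young's modulus (MPa) and Poisson's ratio.
#' @param E_cart,nu_cart cartilage Young's modulus (MPa) and Poisson's ratio.
#' @param E_soft,nu_soft soft-tissue Young's modulus (MPa) and Poisson's ratio
#'   (`nu_soft < 0.5` strictly).
#' @param G_scale scale factor on the Prony relaxation weights.
#' @param x_adv prescribed anterior advancement of the mobile segment (mm).
#' @param prony series used to check `G_scale * sum(g) < 1`.
#' @return named numeric vector of class `input_vector`.
#' @export
input_vector <- function(E_bone = 10000, nu_bone = 0.3,
                         E_cart = 2.75, nu_cart = 0.32,
                         E_soft = 0.55, nu_soft = 0.4745,
                         G_scale = 1, x_adv = 4.6,
                         prony = prony_series()) {
  v <- c(E_bone = E_bone, nu_bone = nu_bone, E_cart = E_cart, nu_cart = nu_cart,
         E_soft = E_soft, nu_soft = nu_soft, G_scale = G_scale, x_adv = x_adv)
  if (any(v[c("E_bone", "E_cart", "E_soft")] <= 0)) stopf("Young's moduli must be positive")
  if (any(v[c("nu_bone", "nu_cart")] <= -1) || any(v[c("nu_bone", "nu_cart")] >= 0.5))
    stopf("Poisson's ratios must lie in (-1, 0.5)")
  if (v["nu_soft"] >= 0.5) stopf("nu_soft must be strictly below 0.5")
  if (v["G_scale"] * sum(prony$g) >= 1)
    stopf("G_scale * sum(g) must be < 1 (long-time modulus positive)")
  structure(v, class = "input_vector")
}

as_input_vector <- function(x, prony = prony_series()) {
  if (inherits(x, "input_vector")) return(x)
  do.call(input_vector, c(as.list(x), list(prony = prony)))
}

# unit constitutive matrices, Voigt order (xx, yy, zz, xy, yz, zx),
# engineering shear strains: C = kappa * m m' + G * Cdev_unit
.C_vol_unit <- {
  m <- c(1, 1, 1, 0, 0, 0)
  tcrossprod(m)
}
.C_dev_unit <- {
  m <- c(1, 1, 1, 0, 0, 0)
  Is <- diag(c(1, 1, 1, 0.5, 0.5, 0.5))
  2 * (Is - tcrossprod(m) / 3)
}

# per-element strain-displacement matrices B (6 x 12) for linear tets,
# vectorised over elements; local dof order (node a, axis d) -> (a-1)*3+d
.tet_B <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  cc <- nodes[tets[, 4], , drop = FALSE] - p1
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cross(b, cc); cxa <- cross(cc, a); axb <- cross(a, b)
  det <- a[, 1] * bxc[, 1] + a[, 2] * bxc[, 2] + a[, 3] * bxc[, 3]
  V <- det / 6
  grads <- array(0, dim = c(nrow(tets), 4L, 3L)) # grad of shape function per node
  grads[, 2L, ] <- bxc / det
  grads[, 3L, ] <- cxa / det
  grads[, 4L, ] <- axb / det
  grads[, 1L, ] <- -(grads[, 2L, ] + grads[, 3L, ] + grads[, 4L, ])
  B <- array(0, dim = c(nrow(tets), 6L, 12L))
  for (aN in 1:4) {
    gx <- grads[, aN, 1L]; gy <- grads[, aN, 2L]; gz <- grads[, aN, 3L]
    cX <- (aN - 1L) * 3L + 1L; cY <- cX + 1L; cZ <- cX + 2L
    B[, 1L, cX] <- gx
    B[, 2L, cY] <- gy
    B[, 3L, cZ] <- gz
    B[, 4L, cX] <- gy; B[, 4L, cY] <- gx
    B[, 5L, cY] <- gz; B[, 5L, cZ] <- gy
    B[, 6L, cX] <- gz; B[, 6L, cZ] <- gx
  }
  list(B = B, V = V)
}

# assemble sum_e V_e B' C B over a subset of elements into a sparse matrix
.assemble_unit <- function(B, V, dof, elems, C, ndof) {
  ne <- length(elems)
  if (ne == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(ndof, ndof), symmetric = TRUE))
  Bs <- B[elems, , , drop = FALSE]
  Vs <- V[elems]
  dofs <- dof[elems, , drop = FALSE]
  CB <- array(0, dim = c(ne, 6L, 12L))
  for (jj in 1:6) {
    nz <- which(C[jj, ] != 0)
    for (bb in 1:12) {
      acc <- 0
      for (kk in nz) acc <- acc + C[jj, kk] * Bs[, kk, bb]
      CB[, jj, bb] <- acc
    }
  }
  iL <- vector("list", 144L); jL <- vector("list", 144L); xL <- vector("list", 144L)
  idx <- 0L
  for (aa in 1:12) {
    for (bb in 1:12) {
      val <- Vs * (Bs[, 1L, aa] * CB[, 1L, bb] + Bs[, 2L, aa] * CB[, 2L, bb] +
                   Bs[, 3L, aa] * CB[, 3L, bb] + Bs[, 4L, aa] * CB[, 4L, bb] +
                   Bs[, 5L, aa] * CB[, 5L, bb] + Bs[, 6L, aa] * CB[, 6L, bb])
      idx <- idx + 1L
      iL[[idx]] <- dofs[, aa]; jL[[idx]] <- dofs[, bb]; xL[[idx]] <- val
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(iL), j = unlist(jL), x = unlist(xL),
                            dims = c(ndof, ndof))
  Matrix::symmpart(K)
}

# volumetric stiffness with patch-averaged volumetric strain (B-bar): the
# volumetric strain is replaced by its volume-weighted average over each patch
# (the 6 tetrahedra of a parent hexahedral cell when the mesh records one,
# otherwise a nodal average), which relaxes the per-element incompressibility
# constraints that lock low-order tets as nu -> 0.5 while keeping the
# stiffness stencil local: K = W' diag(V_patch) W with W the patch-averaged
# divergence rows.
.assemble_bbar_vol <- function(B, V, dof, elems, ndof, tets, cell = NULL) {
  ne <- length(elems)
  if (ne == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(ndof, ndof), symmetric = TRUE))
  Bs <- B[elems, , , drop = FALSE]
  Vs <- V[elems]
  dofs <- dof[elems, , drop = FALSE]
  Bdiv <- Bs[, 1L, ] + Bs[, 2L, ] + Bs[, 3L, ] # ne x 12 divergence rows
  if (!is.null(cell)) {
    patch <- match(cell[elems], unique(cell[elems]))
  } else {
    # fall back: each element its own patch (no averaging)
    patch <- seq_len(ne)
  }
  np <- max(patch)
  Vp <- as.vector(rowsum(Vs, patch))
  w <- as.vector(Bdiv) * (Vs / Vp[patch]) # volume-weighted average coefficients
  W <- Matrix::sparseMatrix(i = rep(patch, 12L), j = as.vector(dofs), x = w,
                            dims = c(np, ndof))
  K <- Matrix::crossprod(Matrix::Diagonal(x = sqrt(Vp)) %*% W)
  Matrix::symmpart(K)
}

#' Precompute the finite-element system for a phantom mesh
#'
#' Builds per-element geometry (strain-displacement matrices, volumes, dof
#' maps) and the region-wise unit stiffness matrices that every solve scales by
#' the realised material properties: deviatoric (unit shear modulus) and
#' volumetric (unit bulk modulus) per region, with a nodal-averaged (B-bar)
#' volumetric treatment on the near-incompressible soft tissue. Building the
#' system once and passing it to repeated solves amortises assembly across a
#' design of experiments.
#'
#' @param mesh a `labeled_tet_mesh`.
#' @return object of class `fem_system`.
#' @export
fem_system <- function(mesh) {
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  geo <- .tet_B(mesh$nodes, mesh$tets)
  dof <- matrix(0L, nrow(mesh$tets), 12L)
  for (aN in 1:4) for (d in 1:3)
    dof[, (aN - 1L) * 3L + d] <- 3L * (mesh$tets[, aN] - 1L) + d
  regions <- c("skull_base", "maxilla_mobile", "cartilage", "soft_tissue")
  elems <- lapply(regions, function(r) which(mesh$region == r))
  names(elems) <- regions
  Kd <- lapply(elems, function(e) .assemble_unit(geo$B, geo$V, dof, e, .C_dev_unit, ndof))
  Kv <- lapply(elems[c("skull_base", "maxilla_mobile", "cartilage")], function(e)
    .assemble_unit(geo$B, geo$V, dof, e, .C_vol_unit, ndof))
  Kv$soft_tissue <- .assemble_bbar_vol(geo$B, geo$V, dof, elems$soft_tissue,
                                       ndof, mesh$tets, cell = mesh$cell)
  .facefem_env$sys_id <- (.facefem_env$sys_id %||% 0L) + 1L
  structure(list(ndof = ndof, n_nodes = nn, B = geo$B, V = geo$V, dof = dof,
                 elems = elems, Kd = Kd, Kv = Kv, id = .facefem_env$sys_id),
            class = "fem_system")
}

#' Boundary conditions replicating the midface fixation planes
#'
#' Fixed (all axes): soft tissue on its posterior, superior and inferior
#' planes; skull base on its posterior and superior planes. Prescribed: the
#' anterior translation applied to all surface nodes of the mobile maxillary
#' segment, ramped linearly over `ramp` seconds and held.
#'
#' @param mesh a `labeled_tet_mesh` with phantom node sets.
#' @param direction unit direction of the prescribed translation (default
#'   anterior, +y).
#' @param ramp load ramp duration (s).
#' @param hold hold duration after the ramp (s).
#' @return object of class `boundary_spec`.
#' @export
default_boundary_spec <- function(mesh, direction = c(0, 1, 0), ramp = 1, hold = 59) {
  ns <- mesh$node_sets
  fixed <- list(
    list(nodes = ns[["soft_tissue.y_min"]], axes = 1:3),
    list(nodes = ns[["soft_tissue.z_max"]], axes = 1:3),
    list(nodes = ns[["soft_tissue.z_min"]], axes = 1:3),
    list(nodes = ns[["skull_base.y_min"]], axes = 1:3),
    list(nodes = ns[["skull_base.z_max"]], axes = 1:3))
  boundary_spec(fixed = fixed,
                prescribed = list(nodes = ns[["maxilla_mobile.surface"]],
                                  direction = direction),
                ramp = ramp, hold = hold)
}

#' General boundary specification
#'
#' @param fixed list of `list(nodes=, axes=)` sets clamped to zero on the
#'   given axes.
#' @param prescribed `list(nodes=, direction=)`: nodes receiving the ramped
#'   translation `x_adv * direction`; only axes with a non-zero direction
#'   component are constrained.
#' @param ramp,hold ramp and hold durations (s).
#' @return object of class `boundary_spec`.
#' @export
boundary_spec <- function(fixed, prescribed, ramp = 1, hold = 59) {
  if (ramp <= 0 || hold < 0) stopf("ramp must be positive and hold non-negative")
  structure(list(fixed = fixed, prescribed = prescribed, ramp = ramp, hold = hold),
            class = "boundary_spec")
}

#' Time grid for the quasi-static viscoelastic solve
#'
#' Linear steps across the load ramp followed by logarithmically spaced steps
#' through the hold; the final time is the reported "postoperative" state.
#'
#' @param ramp ramp duration (s).
#' @param t_end end of hold (s); default 60 s = 10 times the longest default
#'   relaxation time, where the default series is within 1e-4 of its long-time
#'   plateau.
#' @param n_steps total number of steps.
#' @return increasing numeric vector of times (excluding t = 0).
#' @export
make_time_grid <- function(ramp = 1, t_end = 60, n_steps = 30) {
  if (t_end <= ramp) stopf("t_end must exceed the ramp duration")
  if (n_steps < 4) stopf("need at least 4 time steps")
  n_ramp <- max(2L, round(0.2 * n_steps))
  n_hold <- n_steps - n_ramp
  tr <- seq(0, ramp, length.out = n_ramp + 1L)[-1L]
  th <- exp(seq(log(ramp), log(t_end), length.out = n_hold + 1L))[-1L]
  c(tr, th)
}

.materials <- function(inputs) {
  iv <- unclass(inputs)
  Gm <- function(E, nu) E / (2 * (1 + nu))
  Km <- function(E, nu) E / (3 * (1 - 2 * nu))
  list(G_bone = Gm(iv["E_bone"], iv["nu_bone"]), k_bone = Km(iv["E_bone"], iv["nu_bone"]),
       G_cart = Gm(iv["E_cart"], iv["nu_cart"]), k_cart = Km(iv["E_cart"], iv["nu_cart"]),
       G_soft = Gm(iv["E_soft"], iv["nu_soft"]), k_soft = Km(iv["E_soft"], iv["nu_soft"]),
       scale = iv["G_scale"], x_adv = iv["x_adv"])
}

# constraint bookkeeping shared by the elastic and viscoelastic solvers
.partition_dofs <- function(bc, ndof) {
  dirn <- bc$prescribed$direction
  p_axes <- which(abs(dirn) > 0)
  p_nodes <- bc$prescribed$nodes
  presc <- as.vector(outer(3L * (p_nodes - 1L), p_axes, `+`))
  up_unit <- rep(dirn[p_axes], each = length(p_nodes)) # per-mm-advancement values
  fixed <- integer(0)
  for (s in bc$fixed) {
    if (length(s$nodes) == 0L) next
    fixed <- c(fixed, as.vector(outer(3L * (s$nodes - 1L), s$axes, `+`)))
  }
  fixed <- setdiff(unique(fixed), presc)
  free <- setdiff(seq_len(ndof), c(presc, fixed))
  if (length(free) == 0L) stopf("no free degrees of freedom")
  list(free = free, presc = presc, fixed = fixed, up_unit = up_unit)
}

.chol_solve_factor <- function(K) {
  tryCatch(suppressWarnings(Matrix::Cholesky(K, LDL = FALSE, perm = TRUE, super = NA)),
           error = function(e)
             stopf(paste("singular stiffness system (%s);",
                         "check that every region is constrained"), conditionMessage(e)))
}

# Solver context for a (mesh, bc) pair: constraint partition plus the eight
# region unit matrices pre-subsetted to the free dofs and aligned on one
# sparsity skeleton, so each run/time-step assembles the stiffness by a plain
# vector combination. Memoised because designs of experiments reuse the same
# mesh and boundary conditions across many solves.
.solver_context <- function(mesh, bc, sys) {
  key <- hash_object(list(sys_id = sys$id, nn = nrow(mesh$nodes),
                          nt = nrow(mesh$tets), bc = bc))
  cache <- .facefem_env$solver_ctx %||% list()
  if (!is.null(cache[[key]])) return(cache[[key]])
  pp <- .partition_dofs(bc, sys$ndof)
  units <- list(d_bone = sys$Kd$skull_base + sys$Kd$maxilla_mobile,
                v_bone = sys$Kv$skull_base + sys$Kv$maxilla_mobile,
                d_cart = sys$Kd$cartilage, v_cart = sys$Kv$cartilage,
                d_soft = sys$Kd$soft_tissue, v_soft = sys$Kv$soft_tissue)
  ff <- lapply(units, function(K) methods::as(K[pp$free, pp$free], "CsparseMatrix"))
  skel <- Reduce(`+`, lapply(ff, abs))
  nfree <- length(pp$free)
  keys_of <- function(M) M@i + as.numeric(nfree) * rep.int(seq_len(ncol(M)) - 1L,
                                                           diff(M@p))
  skel_keys <- keys_of(skel)
  xcols <- lapply(ff, function(M) {
    x <- numeric(length(skel_keys))
    x[match(keys_of(M), skel_keys)] <- M@x
    x
  })
  wvecs <- lapply(units, function(K)
    as.vector(K[pp$free, pp$presc, drop = FALSE] %*% pp$up_unit))
  ctx <- list(pp = pp, skel = skel, xcols = xcols, wvecs = wvecs)
  cache[[key]] <- ctx
  if (length(cache) > 8L) cache <- cache[length(cache)] # keep the cache small
  .facefem_env$solver_ctx <- cache
  ctx
}

# stiffness (free-free block) and prescribed-coupling vector at a given
# soft-tissue shear factor
.ctx_system <- function(ctx, mat, alpha) {
  co <- c(d_bone = unname(mat$G_bone), v_bone = unname(mat$k_bone),
          d_cart = unname(mat$G_cart), v_cart = unname(mat$k_cart),
          d_soft = unname(alpha * mat$G_soft), v_soft = unname(mat$k_soft))
  x <- 0
  w <- 0
  for (nm in names(co)) {
    x <- x + co[[nm]] * ctx$xcols[[nm]]
    w <- w + co[[nm]] * ctx$wvecs[[nm]]
  }
  K <- ctx$skel
  K@x <- x
  list(K = K, w = w)
}

#' Single elastic solve at a fixed shear factor
#'
#' Solves the linear elastic problem with the soft-tissue shear modulus scaled
#' by `shear_factor`: `1` gives the instantaneous (unrelaxed) response,
#' `1 - G_scale * sum(g)` the long-time (fully relaxed) response. Serves as the
#' static reference the time-stepping solver is verified against.
#'
#' @param mesh a `labeled_tet_mesh`.
#' @param bc a `boundary_spec`.
#' @param inputs an [input_vector()].
#' @param shear_factor multiplier on the soft-tissue shear modulus.
#' @param system optional precomputed [fem_system()].
#' @return a `displacement_field` with a single stored time.
#' @export
solve_elastic <- function(mesh, bc, inputs, shear_factor = 1, system = NULL) {
  inputs <- as_input_vector(inputs)
  sys <- system %||% fem_system(mesh)
  mat <- .materials(inputs)
  ctx <- .solver_context(mesh, bc, sys)
  ks <- .ctx_system(ctx, mat, shear_factor)
  rhs <- -mat$x_adv * ks$w
  ch <- .chol_solve_factor(ks$K)
  uf <- as.vector(Matrix::solve(ch, rhs))
  u <- numeric(sys$ndof)
  u[ctx$pp$free] <- uf
  u[ctx$pp$presc] <- ctx$pp$up_unit * mat$x_adv
  .bump_solve_count()
  structure(list(times = Inf, U = matrix(u, ncol = 1L), n_nodes = sys$n_nodes),
            class = "displacement_field")
}

#' Quasi-static linear viscoelastic solve
#'
#' Region-wise linear elasticity with deviatoric-only Prony-series relaxation
#' in the soft tissue (no volumetric relaxation), integrated with the standard
#' internal-variable exponential recurrence: per step the effective soft-tissue
#' shear factor is `g_inf' + sum_i g_i' beta_i(dt)` with
#' `beta_i = (1 - exp(-dt/tau_i)) tau_i / dt` and the decayed internal
#' variables enter the right-hand side as a history force. The prescribed
#' translation ramps linearly over `bc$ramp` and is then held; the final stored
#' time is the "postoperative" prediction.
#'
#' @param mesh a `labeled_tet_mesh`.
#' @param bc a `boundary_spec`.
#' @param inputs an [input_vector()].
#' @param prony a [prony_series()]; scaled by `inputs["G_scale"]`.
#' @param time_grid increasing times from [make_time_grid()].
#' @param system optional precomputed [fem_system()].
#' @return object of class `displacement_field`: `times`, `U` (ndof-by-nt
#'   matrix of displacements, mm), `n_nodes`.
#' @export
solve_viscoelastic <- function(mesh, bc, inputs, prony = prony_series(),
                               time_grid = make_time_grid(), system = NULL) {
  inputs <- as_input_vector(inputs, prony = prony)
  if (is.unsorted(time_grid, strictly = TRUE) || any(time_grid <= 0))
    stopf("time_grid must be strictly increasing and positive")
  if (max(time_grid) < bc$ramp) stopf("time grid must cover the load ramp")
  sys <- system %||% fem_system(mesh)
  mat <- .materials(inputs)
  ctx <- .solver_context(mesh, bc, sys)
  pp <- ctx$pp
  up1 <- pp$up_unit * mat$x_adv # prescribed values at full load

  se <- sys$elems$soft_tissue
  ne_s <- length(se)
  Bs <- sys$B[se, , , drop = FALSE]
  Vs <- sys$V[se]
  dof_s <- sys$dof[se, , drop = FALSE]
  gsc <- mat$scale * prony$g
  g_inf <- 1 - sum(gsc)

  eps_prev <- matrix(0, ne_s, 6L)
  r <- lapply(seq_len(prony$n), function(i) matrix(0, ne_s, 6L))
  nt <- length(time_grid)
  U <- matrix(0, sys$ndof, nt)
  ch <- NULL
  alpha_prev <- NA_real_
  t_prev <- 0
  Cd <- .C_dev_unit

  elem_strains <- function(u) {
    ue <- matrix(u[dof_s], ne_s, 12L)
    eps <- matrix(0, ne_s, 6L)
    for (jj in 1:6) {
      acc <- 0
      for (aa in 1:12) acc <- acc + Bs[, jj, aa] * ue[, aa]
      eps[, jj] <- acc
    }
    eps
  }

  for (k in seq_len(nt)) {
    tk <- time_grid[k]
    dt <- tk - t_prev
    Ei <- exp(-dt / prony$tau)
    beta <- (1 - Ei) * prony$tau / dt
    alpha <- g_inf + sum(gsc * beta)
    # history strain and its force contribution
    h <- matrix(0, ne_s, 6L)
    for (i in seq_len(prony$n)) h <- h + Ei[i] * r[[i]]
    h <- h - sum(gsc * beta) * eps_prev
    s_h <- mat$G_soft * (h %*% Cd) # Cd symmetric: s = G0 * Cd %*% h per element
    fe <- matrix(0, ne_s, 12L)
    for (aa in 1:12) {
      acc <- 0
      for (jj in 1:6) acc <- acc + Bs[, jj, aa] * s_h[, jj]
      fe[, aa] <- Vs * acc
    }
    Fh <- numeric(sys$ndof)
    agg <- rowsum(as.vector(fe), group = as.vector(dof_s))
    Fh[as.integer(rownames(agg))] <- agg[, 1L]

    ramp_frac <- min(tk / bc$ramp, 1)
    ks <- .ctx_system(ctx, mat, alpha)
    rhs <- -Fh[pp$free] - ramp_frac * mat$x_adv * ks$w
    if (is.null(ch) || alpha != alpha_prev) ch <- .chol_solve_factor(ks$K)
    alpha_prev <- alpha
    uf <- as.vector(Matrix::solve(ch, rhs))
    u <- numeric(sys$ndof)
    u[pp$free] <- uf
    u[pp$presc] <- ramp_frac * up1
    U[, k] <- u

    eps_new <- elem_strains(u)
    deps <- eps_new - eps_prev
    for (i in seq_len(prony$n)) r[[i]] <- Ei[i] * r[[i]] + gsc[i] * beta[i] * deps
    eps_prev <- eps_new
    t_prev <- tk
  }
  .bump_solve_count()
  structure(list(times = time_grid, U = U, n_nodes = sys$n_nodes),
            class = "displacement_field")
}

#' Extract landmark displacements from a displacement field
#'
#' Returns the signed anterior (y) displacement component at each landmark
#' node at the final stored time: the preoperative baseline is 0 mm.
#'
#' @param field a `displacement_field`.
#' @param landmarks a `landmark_set`.
#' @param component `"y"` (default, signed anterior) or `"magnitude"`.
#' @return named numeric of length 5 (N, UL, LL, RC, LC), mm.
#' @export
extract_landmarks <- function(field, landmarks, component = c("y", "magnitude")) {
  component <- match.arg(component)
  idx <- as.integer(unclass(landmarks))
  if (any(idx < 1L) || any(idx > field$n_nodes)) stopf("landmark node index out of range")
  u <- field$U[, ncol(field$U)]
  out <- if (component == "y") {
    u[3L * (idx - 1L) + 2L]
  } else {
    sqrt(u[3L * (idx - 1L) + 1L]^2 + u[3L * (idx - 1L) + 2L]^2 + u[3L * (idx - 1L) + 3L]^2)
  }
  names(out) <- names(landmarks)
  out
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("displacement_field:", x$n_nodes, "nodes,", length(x$times), "stored times",
      sprintf("(final t = %g s)\n", x$times[length(x$times)]))
  invisible(x)
}
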