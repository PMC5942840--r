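test_that("shear relaxation follows the two-term Prony arithmetic", {
  pr <- prony_series()
  expect_equal(shear_relaxation(0, pr, scale = 1), 1.0)
  expect_equal(shear_relaxation(1e6, pr, scale = 1), 0.375, tolerance = 1e-10)
  expect_equal(shear_relaxation(1e6, pr, scale = 0.488), 0.695, tolerance = 1e-10)
  expect_equal(shear_relaxation(1, pr, scale = 1),
               1 - 0.325 * (1 - exp(-1)) - 0.3 * (1 - exp(-1 / 6)))
  ts <- seq(0, 100, length.out = 200)
  expect_true(all(diff(shear_relaxation(ts, pr, 1.2)) <= 0))
  expect_error(shear_relaxation(-1, pr), "negative")
  expect_error(shear_relaxation(1, pr, scale = 1.7), "long-time")
  expect_error(prony_series(g = c(0.6, 0.5)), "< 1")
})

test_that("uniaxial elastic block matches the closed-form solution", {
  bm <- block_mesh(lx = 10, ly = 20, lz = 10, edge = 2.5)
  sys <- fem_system(bm)
  bc <- boundary_spec(
    fixed = list(list(nodes = bm$node_sets[["soft_tissue.y_min"]], axes = 2L),
                 list(nodes = bm$node_sets[["soft_tissue.x_min"]], axes = 1L),
                 list(nodes = bm$node_sets[["soft_tissue.z_min"]], axes = 3L)),
    prescribed = list(nodes = bm$node_sets[["soft_tissue.y_max"]],
                      direction = c(0, 1, 0)))
  nu <- 0.45
  f <- solve_elastic(bm, bc, input_vector(E_soft = 0.5, nu_soft = nu, x_adv = 1),
                     system = sys)
  u <- matrix(f$U[, 1], ncol = 3, byrow = TRUE)
  exact <- cbind(-nu * bm$nodes[, 1] / 20, bm$nodes[, 2] / 20,
                 -nu * bm$nodes[, 3] / 20)
  expect_lt(max(abs(u - exact)) / max(abs(exact)), 0.005)
})

test_that("end-of-hold viscoelastic state matches the long-time elastic solve", {
  ctx <- tiny_ctx()
  iv <- input_vector(G_scale = 1.2, x_adv = 5)
  visc <- extract_landmarks(
    solve_viscoelastic(ctx$mesh, ctx$bc, iv, time_grid = ctx$tg, system = ctx$sys),
    ctx$landmarks)
  ginf <- 1 - 1.2 * sum(prony_series()$g)
  elas <- extract_landmarks(
    solve_elastic(ctx$mesh, ctx$bc, iv, shear_factor = ginf, system = ctx$sys),
    ctx$landmarks)
  expect_rel_close(visc, elas, 0.01)
})

test_that("instantaneous response matches the unrelaxed elastic solve", {
  ctx <- tiny_ctx()
  iv <- input_vector(x_adv = 4)
  bc_fast <- default_boundary_spec(ctx$mesh, ramp = 1e-3, hold = 60)
  tg <- make_time_grid(ramp = 1e-3, t_end = 60, n_steps = 12)
  f <- solve_viscoelastic(ctx$mesh, bc_fast, iv, time_grid = tg, system = ctx$sys)
  k_ramp_end <- max(which(tg <= 1e-3 + 1e-12))
  idx <- as.integer(ctx$landmarks)
  inst <- f$U[3L * (idx - 1L) + 2L, k_ramp_end]
  elas <- extract_landmarks(
    solve_elastic(ctx$mesh, ctx$bc, iv, shear_factor = 1, system = ctx$sys),
    ctx$landmarks)
  expect_rel_close(inst, unname(elas), 0.01)
})

test_that("prescribed-displacement loading is invariant to a joint modulus scaling", {
  ctx <- tiny_ctx()
  iv1 <- input_vector(x_adv = 4)
  iv2 <- iv1
  iv2[c("E_bone", "E_cart", "E_soft")] <- 2 * iv2[c("E_bone", "E_cart", "E_soft")]
  y1 <- tiny_landmarks_solve(iv1)
  y2 <- tiny_landmarks_solve(input_vector(E_bone = iv2[["E_bone"]],
                                          E_cart = iv2[["E_cart"]],
                                          E_soft = iv2[["E_soft"]], x_adv = 4))
  expect_rel_close(y1, y2, 1e-8)
})

test_that("landmark displacements are monotone in the advancement", {
  ys <- vapply(c(2, 4, 6), function(a) tiny_landmarks_solve(input_vector(x_adv = a)),
               numeric(5))
  for (i in 1:5) expect_true(all(diff(ys[i, ]) > 0))
  # and the upper lip tracks the advancement within the rigid-attachment bracket
  y4 <- ys[, 2]
  expect_gt(y4[["UL"]], 0.5 * 4)
  expect_lt(y4[["UL"]], 1.1 * 4)
})

test_that("landmark extraction handles zero and rigid-translation fields", {
  ctx <- tiny_ctx()
  nn <- nrow(ctx$mesh$nodes)
  zero <- structure(list(times = 1, U = matrix(0, 3 * nn, 1), n_nodes = nn),
                    class = "displacement_field")
  expect_equal(unname(extract_landmarks(zero, ctx$landmarks)), rep(0, 5))
  u <- rep(c(0, 2.5, 0), nn)
  rigid <- structure(list(times = 1, U = matrix(u, ncol = 1), n_nodes = nn),
                     class = "displacement_field")
  expect_equal(unname(extract_landmarks(rigid, ctx$landmarks)), rep(2.5, 5))
  expect_equal(unname(extract_landmarks(rigid, ctx$landmarks,
                                        component = "magnitude")), rep(2.5, 5))
})

test_that("solver is deterministic and counts solves", {
  ctx <- tiny_ctx()
  iv <- input_vector(x_adv = 3)
  fem_solve_count(reset = TRUE)
  f1 <- solve_viscoelastic(ctx$mesh, ctx$bc, iv, time_grid = ctx$tg, system = ctx$sys)
  f2 <- solve_viscoelastic(ctx$mesh, ctx$bc, iv, time_grid = ctx$tg, system = ctx$sys)
  expect_identical(f1$U, f2$U)
  expect_equal(fem_solve_count(), 2L)
})

test_that("halving the mesh edge length changes each landmark by less than 5%", {
  iv <- input_vector(x_adv = 4.6)
  res <- lapply(c(5, 2.5), function(e) {
    ph <- build_phantom(phantom_geometry(edge = e))
    sys <- fem_system(ph$mesh)
    bc <- default_boundary_spec(ph$mesh)
    f <- solve_viscoelastic(ph$mesh, bc, iv,
                            time_grid = make_time_grid(n_steps = 12),
                            system = sys)
    extract_landmarks(f, ph$landmarks)
  })
  expect_lt(max(abs(res[[2]] - res[[1]]) / abs(res[[2]])), 0.05)
})

test_that("an unconstrained system raises an informative error", {
  bm <- block_mesh(lx = 10, ly = 10, lz = 10, edge = 5)
  bc <- boundary_spec(
    fixed = list(),
    prescribed = list(nodes = bm$node_sets[["soft_tissue.y_max"]],
                      direction = c(0, 1, 0)))
  expect_error(solve_elastic(bm, bc, input_vector(x_adv = 1)),
               "singular|constrained")
})
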