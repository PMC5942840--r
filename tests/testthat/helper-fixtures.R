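# Shared fixtures, built once per test session.
# The "tiny" phantom is a down-scaled geometry with landmarks placed so that
# nearest-node snapping is tie-free at edge = 8 mm.

.fx <- new.env(parent = emptyenv())

tiny_geometry <- function(edge = 8) {
  phantom_geometry(width = 48, height = 48, bone_depth = 10, soft_depth = 15,
                   bone_zmin = 8, cut_z = 24, gap = 6,
                   cartilage = list(half_width = 8, z = c(30, 38), depth = 8),
                   aperture = list(half_width = 8, z_top = 40),
                   landmarks = list(N = c(0, 33), UL = c(0, 16), LL = c(0, 6),
                                    RC = c(14, 34), LC = c(-14, 34)),
                   edge = edge)
}

# memoised tiny solver context: phantom + system + bc + a short time grid
tiny_ctx <- function() {
  if (is.null(.fx$tiny)) {
    ph <- build_phantom(tiny_geometry())
    sys <- fem_system(ph$mesh)
    bc <- default_boundary_spec(ph$mesh)
    .fx$tiny <- list(ph = ph, mesh = ph$mesh, landmarks = ph$landmarks,
                     sys = sys, bc = bc,
                     tg = make_time_grid(n_steps = 12))
  }
  .fx$tiny
}

tiny_landmarks_solve <- function(inputs, n_steps = 12) {
  ctx <- tiny_ctx()
  f <- solve_viscoelastic(ctx$mesh, ctx$bc, inputs, system = ctx$sys,
                          time_grid = make_time_grid(n_steps = n_steps))
  extract_landmarks(f, ctx$landmarks)
}

# analytic 4-input toy response used for surrogate/MOGA tests
toy_bounds <- function() {
  list(E_cart = c(0.5, 5), E_soft = c(0.1, 1),
       nu_soft = c(0.45, 0.499), G_scale = c(0.488, 1.512))
}

toy_response <- function(X) {
  cbind(N = 0.2 + 0.3 * X[, "E_cart"] - 0.5 * X[, "E_soft"] + 2 * X[, "nu_soft"],
        UL = 4 + 0.2 * X[, "G_scale"] + 0.1 * X[, "E_soft"]^2,
        RC = 0.1 + 0.05 * X[, "E_cart"] * X[, "G_scale"],
        LC = 0.1 + 0.04 * X[, "E_cart"] + 0.3 * X[, "nu_soft"])
}

# micro pipeline configuration for fast end-to-end plumbing tests
micro_config <- function(outdir, seed = 1L) {
  pipeline_config(preset = "desk", seed = seed, outdir = outdir,
                  geometry = tiny_geometry(),
                  screening_n = 12L, doe1_n = 12L, doe2_n = 10L,
                  moga = moga_config(population = 120L, max_iterations = 3L,
                                     n_extract = 40L),
                  n_steps = 8L,
                  selected = c("E_cart", "E_soft", "G_scale", "x_adv"))
}

expect_rel_close <- function(a, b, tol) {
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), tol)
}
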