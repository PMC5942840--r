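test_that("phantom invariants hold across a grid of geometry parameters", {
  geoms <- list(
    phantom_geometry(edge = 10),
    phantom_geometry(edge = 8),
    phantom_geometry(width = 60, height = 80, edge = 10),
    phantom_geometry(cut_z = 35, gap = 6, edge = 10),
    tiny_geometry())
  for (g in geoms) {
    ph <- build_phantom(g)
    expect_true(validate_phantom(ph$mesh, ph$landmarks))
    expect_setequal(unique(ph$mesh$region),
                    c("skull_base", "maxilla_mobile", "cartilage", "soft_tissue"))
    # mobile segment lies strictly below the skull base, separated by the gap
    mob <- unique(as.vector(ph$mesh$tets[ph$mesh$region == "maxilla_mobile", ]))
    base <- unique(as.vector(ph$mesh$tets[ph$mesh$region == "skull_base", ]))
    expect_lt(max(ph$mesh$nodes[mob, 3]), min(ph$mesh$nodes[base, 3]))
    expect_lte(max(ph$mesh$nodes[mob, 3]), g$cut_z + g$edge + 1e-9)
  }
})

test_that("mesh node grid is mirror-symmetric about the midline", {
  ph <- build_phantom(phantom_geometry(edge = 10))
  nd <- ph$mesh$nodes
  mirrored <- cbind(-nd[, 1], nd[, 2], nd[, 3])
  key <- function(m) sort(paste(round(m[, 1], 9), round(m[, 2], 9), round(m[, 3], 9)))
  expect_identical(key(nd), key(mirrored))
})

test_that("degenerate geometry parameters raise explicit errors", {
  expect_error(phantom_geometry(width = -10), "degenerate")
  expect_error(phantom_geometry(cut_z = 90), "osteotomy")
  expect_error(phantom_geometry(cartilage = list(half_width = 10, z = c(50, 60),
                                                 depth = 20)), "cartilage")
  expect_error(build_phantom(phantom_geometry(width = 30, height = 30,
                                              bone_zmin = 5, cut_z = 12, gap = 4,
                                              cartilage = list(half_width = 6,
                                                               z = c(16, 22),
                                                               depth = 6),
                                              landmarks = list(N = c(0, 20),
                                                               UL = c(0, 9),
                                                               LL = c(0, 2),
                                                               RC = c(8, 21),
                                                               LC = c(-8, 21)),
                                              edge = 14)),
               "coarse|nodes")
})

test_that("cohort fixture reproduces the reference interval statistics", {
  tab <- load_cohort_table()
  expect_equal(nrow(tab), 8L)
  expect_equal(summarize_column(tab, "surgery_to_postop_days", "mean", "integer"), 67)
  expect_equal(summarize_column(tab, "surgery_to_postop_days", "sd", "integer"), 23)
  expect_equal(summarize_column(tab, "planned_advancement_mm", "mean", "1dp"), 4.6)
  expect_error(summarize_column(tab, "no_such_column", "mean"), "unknown column")
  expect_error(summarize_column(tab, "age_years", "median"), "arg")
})

test_that("synthetic truth equals the forward solve at zero noise", {
  ctx <- tiny_ctx()
  iv <- input_vector(x_adv = 4)
  truth <- synthesize_truth(ctx$mesh, ctx$landmarks, iv, noise_sd = 0,
                            time_grid = ctx$tg, system = ctx$sys)
  direct <- extract_landmarks(
    solve_viscoelastic(ctx$mesh, ctx$bc, iv, time_grid = ctx$tg, system = ctx$sys),
    ctx$landmarks)
  expect_identical(truth, direct)
})

test_that("zero advancement produces (near) zero targets", {
  ctx <- tiny_ctx()
  iv <- input_vector(x_adv = 0)
  truth <- synthesize_truth(ctx$mesh, ctx$landmarks, iv, noise_sd = 0,
                            time_grid = ctx$tg, system = ctx$sys)
  expect_true(all(abs(truth) < 1e-10))
})

test_that("truth noise has the configured standard deviation", {
  ctx <- tiny_ctx()
  iv <- input_vector(x_adv = 4)
  base <- synthesize_truth(ctx$mesh, ctx$landmarks, iv, noise_sd = 0,
                           time_grid = ctx$tg, system = ctx$sys)
  noise <- t(vapply(1:100, function(s)
    synthesize_truth(ctx$mesh, ctx$landmarks, iv, noise_sd = 0.2, seed = s,
                     time_grid = ctx$tg, system = ctx$sys) - base,
    numeric(5)))
  sds <- apply(noise, 2L, sd)
  expect_true(all(sds > 0.15 & sds < 0.25))
})
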