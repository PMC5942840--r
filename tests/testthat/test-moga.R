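test_that("a planted optimum is recovered to within 1% of each range", {
  b <- toy_bounds()
  d <- sample_design(b, n_samples = 27, seed = 5)
  sur <- fit_surrogate(d, toy_response(d$samples))
  xstar <- c(E_cart = 2.2, E_soft = 0.7, nu_soft = 0.47, G_scale = 1.1)
  tg <- setNames(as.vector(toy_response(t(as.matrix(xstar)))),
                 c("N", "UL", "RC", "LC"))
  pc <- optimize_materials(sur, optimization_targets(tg), b,
                           config = moga_config(population = 500L), seed = 7)
  span <- vapply(b, diff, numeric(1))
  expect_true(all(abs(pc$X[1, ] - xstar) / span < 0.01))
  expect_equal(nrow(pc$X), 100L)
})

test_that("an unreachable target drives candidates to the bound of the driving input", {
  # N increases only with E_cart; the other landmarks do not involve E_cart,
  # so pushing E_cart to its maximum costs nothing on the other objectives
  b <- toy_bounds()
  d <- sample_design(b, n_samples = 27, seed = 6)
  X <- d$samples
  resp <- function(X) cbind(N = 0.5 * X[, "E_cart"],
                            UL = 4 + 0.2 * X[, "G_scale"],
                            RC = 1 + X[, "E_soft"],
                            LC = 2 * X[, "nu_soft"])
  sur <- fit_surrogate(d, resp(X))
  tg <- c(N = 100, UL = 4.2, RC = 1.5, LC = 0.95)
  pc <- optimize_materials(sur, optimization_targets(tg), b,
                           config = moga_config(population = 400L,
                                                n_extract = 50L), seed = 2)
  # the top-ranked candidates sit against the upper bound of the driving input
  expect_gt(stats::median(pc$X[1:10, "E_cart"]), 0.5 + 0.9 * 4.5)
})

test_that("the returned candidate set stays in bounds, is front-ranked and reproducible", {
  b <- toy_bounds()
  d <- sample_design(b, n_samples = 27, seed = 5)
  sur <- fit_surrogate(d, toy_response(d$samples))
  tg <- c(N = 1.5, UL = 4.3, RC = 0.3, LC = 0.35)
  cfg <- moga_config(population = 300L, n_extract = 60L)
  pc1 <- optimize_materials(sur, optimization_targets(tg), b, config = cfg, seed = 3)
  pc2 <- optimize_materials(sur, optimization_targets(tg), b, config = cfg, seed = 3)
  expect_identical(pc1$X, pc2$X)
  for (nm in colnames(pc1$X))
    expect_true(all(pc1$X[, nm] >= b[[nm]][1] & pc1$X[, nm] <= b[[nm]][2]))
  expect_true(all(pc1$rank <= 2L))
  # surrogate predictions over the candidates stay inside the DOE prediction range
  nd <- as.data.frame(pc1$X)
  P <- predict(sur, nd, outputs = c("N", "UL", "RC", "LC"))
  Ytr <- toy_response(d$samples)
  for (nm in colnames(P)) {
    expect_gte(min(P[, nm]), min(Ytr[, nm]) - 0.05 * diff(range(Ytr[, nm])))
    expect_lte(max(P[, nm]), max(Ytr[, nm]) + 0.05 * diff(range(Ytr[, nm])))
  }
})

test_that("LL is excluded from optimisation and small populations error", {
  expect_error(optimization_targets(c(N = 1, UL = 2, RC = 1, LC = 1, LL = 0),
                                    include = c("N", "LL")), "LL")
  expect_error(moga_config(population = 50L), "n_extract")
})

test_that("the Pareto front of a convex bi-objective problem is well covered", {
  zdt1 <- function(X) {
    f1 <- X[, 1]
    g <- 1 + 9 * rowMeans(X[, -1, drop = FALSE])
    cbind(f1, g * (1 - sqrt(f1 / g)))
  }
  r <- nsga2_minimize(zdt1, rep(0, 4), rep(1, 4), pop_size = 200, max_gen = 50,
                      seed = 11, stability_pct = 0.1, pareto_pct = 95)
  Fp <- r$F[r$rank == 1L, , drop = FALSE]
  ref <- c(1.1, 1.1)
  hv <- function(F) {
    F <- F[F[, 1] <= ref[1] & F[, 2] <= ref[2], , drop = FALSE]
    F <- F[order(F[, 1]), , drop = FALSE]
    F <- F[cummin(F[, 2]) == F[, 2], , drop = FALSE]
    sum((c(F[-1, 1], ref[1]) - F[, 1]) * (ref[2] - F[, 2]))
  }
  hv_exact <- 0.1 + 2 / 3 + 0.11 # reference box minus the area under f2 = 1 - sqrt(f1)
  expect_gte(hv(Fp) / hv_exact, 0.95)
})
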