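test_that("a quadratic response is recovered exactly by the polynomial family", {
  b <- list(a = c(0, 1), b = c(-2, 2))
  d <- sample_design(b, n_samples = 27, seed = 3)
  X <- d$samples
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + 3 * X[, 1]^2 + X[, 1] * X[, 2]
  sur <- fit_surrogate(d, cbind(out = y))
  expect_identical(sur$models$out$kind, "poly")
  expect_lt(sur$models$out$cv_rmse, 1e-6)
  probe <- facefem:::with_seed(8, cbind(a = runif(100), b = runif(100, -2, 2)))
  truth <- 1 + 2 * probe[, 1] - 0.5 * probe[, 2] + 3 * probe[, 1]^2 +
    probe[, 1] * probe[, 2]
  expect_lt(max(abs(predict(sur, probe)[, 1] - truth)), 1e-6)
})

test_that("a constant response yields a constant predictor with zero CV error", {
  b <- list(a = c(0, 1), b = c(0, 1))
  d <- sample_design(b, n_samples = 12, seed = 1)
  sur <- fit_surrogate(d, cbind(out = rep(3.5, 12)))
  expect_identical(sur$models$out$kind, "constant")
  expect_equal(sur$models$out$cv_rmse, 0)
  expect_equal(unname(predict(sur, d$samples[1:3, ])[, 1]), rep(3.5, 3))
})

test_that("a rank-deficient polynomial basis falls back to the GP family", {
  b <- list(a = c(0, 1), b = c(0, 1))
  X <- cbind(a = seq(0, 1, length.out = 12), b = rep(0.5, 12))
  y <- sin(2 * X[, 1])
  sur <- fit_surrogate(X, cbind(out = y), bounds = b)
  expect_identical(sur$models$out$kind, "gp")
  expect_true(is.finite(sur$models$out$cv_rmse))
})

test_that("surrogate CV error is small relative to the toy response range", {
  d <- sample_design(toy_bounds(), n_samples = 27, seed = 5)
  Y <- toy_response(d$samples)
  sur <- fit_surrogate(d, Y)
  for (nm in colnames(Y)) {
    rng <- diff(range(Y[, nm]))
    expect_lt(sur$models[[nm]]$cv_rmse, 0.05 * rng)
  }
})
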