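test_that("pooling stacks candidate matrices row-wise and checks columns", {
  m <- matrix(runif(400), 100, 4,
              dimnames = list(NULL, c("E_cart", "E_soft", "nu_soft", "G_scale")))
  pooled <- pool_candidates(rep(list(m), 5))
  expect_equal(dim(pooled), c(500L, 4L))
  expect_equal(pool_candidates(list(m)), m)
  m2 <- m[, c(2, 1, 3, 4)]
  expect_error(pool_candidates(list(m, m2)), "mismatched columns")
})

test_that("3-parameter Weibull MLE recovers shape, scale and location", {
  x <- facefem:::with_seed(42, rweibull(500, 2, 1))
  f <- fit_weibull(x, bounds = c(0, 10))
  expect_gt(f$shape, 1.8); expect_lt(f$shape, 2.2)
  expect_gt(f$scale, 0.93); expect_lt(f$scale, 1.07)
  expect_lt(f$location, min(x))
  # shifted sample emulating the Poisson's-ratio support
  x2 <- facefem:::with_seed(7, 0.45 + rweibull(500, 1.8, 0.02))
  f2 <- fit_weibull(x2, bounds = c(0.45, 0.499))
  expect_lt(abs(f2$location - 0.45), 0.01)
})

test_that("degenerate inputs to the Weibull fit raise errors", {
  expect_error(fit_weibull(rep(1, 100), bounds = c(0, 2)), "constant")
  expect_error(fit_weibull(rweibull(10, 2, 1), bounds = c(0, 10)), "pool")
})

test_that("bounded sampling matches the analytic mean and is reproducible", {
  f <- structure(list(shape = 2, scale = 1, location = 0.5, bounds = c(0, 100)),
                 class = "weibull_fit")
  s <- sample_distribution(f, 1e5, seed = 9)
  analytic <- 0.5 + gamma(1.5)
  expect_lt(abs(mean(s) - analytic) / analytic, 0.01)
  expect_equal(attr(s, "rejections"), 0L)
  s1 <- sample_distribution(f, 50, seed = 3)
  s2 <- sample_distribution(f, 50, seed = 3)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_error(sample_distribution(f, 10, bounds = c(50, 100), seed = 1),
               "99.9")
})

test_that("fit -> sample -> refit round trip recovers shape and scale within 15%", {
  x <- facefem:::with_seed(5, 1 + rweibull(400, 1.6, 0.5))
  f <- fit_weibull(x, bounds = c(1, 10))
  s <- as.numeric(sample_distribution(f, 500, seed = 21))
  f2 <- fit_weibull(s, bounds = c(1, 10))
  expect_lt(abs(f2$shape - f$shape) / f$shape, 0.15)
  expect_lt(abs(f2$scale - f$scale) / f$scale, 0.15)
})
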