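test_that("design sizing follows the central-composite rule", {
  expect_identical(design_size(5), 27L)
  expect_identical(design_size(4), 25L)
  expect_identical(design_size(6), 45L)
  expect_identical(design_size(1), 5L)
  expect_error(design_size(0), ">= 1")
})

test_that("sampled designs are Latin, in bounds and reproducible", {
  b <- c(material_bounds()[c("E_cart", "E_soft", "nu_soft", "G_scale")],
         list(x_adv = c(3, 7)))
  d <- sample_design(b, n_samples = 27, seed = 4)
  X <- d$samples
  expect_equal(dim(X), c(27L, 5L))
  for (nm in names(b)) {
    x <- X[, nm]
    expect_true(all(x >= b[[nm]][1] & x <= b[[nm]][2]))
    # Latin property: exactly one point per equal-probability stratum
    u <- (x - b[[nm]][1]) / diff(b[[nm]])
    strata <- findInterval(u, seq(0, 1, length.out = 28), rightmost.closed = TRUE)
    expect_equal(sort(strata), 1:27)
  }
  expect_identical(sample_design(b, n_samples = 27, seed = 4)$samples, X)
  expect_false(identical(sample_design(b, n_samples = 27, seed = 5)$samples, X))
  expect_error(sample_design(list(a = c(2, 1)), 10), "bounds")
})

test_that("maximin restart search does not fall below the plain LHS", {
  b <- list(a = c(0, 1), b = c(0, 1), c = c(0, 1))
  d <- sample_design(b, n_samples = 20, seed = 9, restarts = 50)
  plain <- facefem:::with_seed(9, lhs::randomLHS(20, 3))
  expect_gte(d$min_distance, min(dist(plain)))
})

test_that("screening flags a perfect monotone dependence and freezes the rest", {
  set.seed(2)
  n <- 40
  X <- cbind(a = runif(n), b = runif(n), c = runif(n))
  Y <- cbind(out1 = exp(X[, "a"]), out2 = rnorm(n))
  scr <- screen_variables(X, Y, bounds = list(a = c(0, 1), b = c(0, 1), c = c(0, 1)))
  row_a <- scr$table[scr$table$input == "a" & scr$table$output == "out1", ]
  expect_equal(row_a$r, 1)
  expect_lt(row_a$p, 0.05)
  expect_true(scr$selected[["a"]])
  expect_true(all(c(scr$table$lo <= scr$table$r, scr$table$r <= scr$table$hi),
                  na.rm = TRUE))
  for (nm in names(scr$frozen)) expect_equal(scr$frozen[[nm]], 0.5)
})

test_that("a constant column yields a warning, not an error, and is not selected", {
  set.seed(3)
  X <- cbind(a = runif(20), b = rep(2, 20))
  Y <- cbind(out = X[, "a"] + rnorm(20, 0, 0.01))
  expect_warning(scr <- screen_variables(X, Y, bounds = list(a = c(0, 1), b = c(1, 3))),
                 "constant")
  expect_false(scr$selected[["b"]])
  expect_error(screen_variables(X[1:5, ], Y[1:5, , drop = FALSE]), "at least 10")
})
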