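# Pooling of optimised candidate matrices across training subjects, 3-parameter
# Weibull fitting per material parameter, and bounded sampling for the second
# design-of-experiments iteration.

#' Pool optimised candidate matrices across training subjects
#'
#' Row-wise superimposition: with 5 subjects of m = 100 candidates each, the
#' pooled matrix has 500 rows per material column.
#'
#' @param candidate_sets list of `pareto_candidates` (or plain matrices with
#'   identical column names in identical order).
#' @return numeric matrix, the vertical concatenation.
#' @export
pool_candidates <- function(candidate_sets) {
  if (length(candidate_sets) == 0L) stopf("no candidate sets to pool")
  mats <- lapply(candidate_sets, function(s) if (inherits(s, "pareto_candidates")) s$X else as.matrix(s))
  ref <- colnames(mats[[1L]])
  if (is.null(ref)) stopf("candidate matrices must have column names")
  for (i in seq_along(mats)) {
    if (!identical(colnames(mats[[i]]), ref))
      stopf("candidate set %d has mismatched columns (%s vs %s)", i,
            paste(colnames(mats[[i]]), collapse = ","), paste(ref, collapse = ","))
  }
  do.call(rbind, mats)
}

#' Fit a location-shifted (3-parameter) Weibull distribution
#'
#' Maximum-likelihood fit with the location parameter profiled on a grid over
#' `[physical min - 10% of the physical range, sample min)` (each grid value
#' fixes the shift, shape and scale are fitted by MLE on the shifted data; the
#' grid optimum is then refined by a one-dimensional search). The shift is
#' needed because parameters such as the soft-tissue Poisson's ratio live on
#' an interval far from zero, which a two-parameter Weibull anchored at the
#' origin cannot represent.
#'
#' @param samples numeric vector (>= 30 values, non-constant).
#' @param bounds physical `c(min, max)` of the parameter.
#' @param n_grid number of location grid points.
#' @return object of class `weibull_fit`: `shape`, `scale`, `location`, `n`,
#'   `ks` (Kolmogorov-Smirnov statistic against the fitted distribution),
#'   `loglik`, `bounds`.
#' @export
fit_weibull <- function(samples, bounds, n_grid = 64L) {
  x <- as.numeric(samples)
  if (length(x) < 30L)
    stopf("need at least 30 samples to fit (pool candidate sets across subjects)")
  if (stats::sd(x) == 0) stopf("constant samples: Weibull fit undefined")
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) stopf("invalid physical bounds")
  smin <- min(x)
  glo <- bounds[1] - 0.1 * diff(bounds)
  if (glo >= smin) glo <- smin - 0.1 * diff(bounds)
  fit_at <- function(loc) {
    xs <- x - loc
    f <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(xs, "weibull",
                                             start = .weibull_start(xs))),
      error = function(e) NULL)
    if (is.null(f)) return(list(loglik = -Inf))
    list(loglik = f$loglik, shape = unname(f$estimate["shape"]),
         scale = unname(f$estimate["scale"]))
  }
  eps <- 1e-9 * max(diff(bounds), 1)
  grid <- seq(glo, smin - eps, length.out = n_grid)
  lls <- vapply(grid, function(l) fit_at(l)$loglik, numeric(1))
  if (all(!is.finite(lls))) stopf("Weibull fit failed at every location grid point")
  ib <- which.max(lls)
  lo <- grid[max(1L, ib - 1L)]
  hi <- min(grid[min(n_grid, ib + 1L)], smin - eps)
  opt <- stats::optimize(function(l) fit_at(l)$loglik, c(lo, hi), maximum = TRUE)
  loc <- if (opt$objective > lls[ib]) opt$maximum else grid[ib]
  best <- fit_at(loc)
  ks <- suppressWarnings(stats::ks.test(x, function(q)
    stats::pweibull(q - loc, shape = best$shape, scale = best$scale)))$statistic
  structure(list(shape = best$shape, scale = best$scale, location = loc,
                 n = length(x), ks = unname(ks), loglik = best$loglik,
                 bounds = bounds),
            class = "weibull_fit")
}

# moment-based starting values for the 2-parameter MLE
.weibull_start <- function(xs) {
  m <- mean(xs); v <- stats::var(xs)
  cv <- sqrt(v) / m
  shape <- if (is.finite(cv) && cv > 0) max(0.1, cv^-1.086) else 1
  scale <- m / gamma(1 + 1 / shape)
  list(shape = shape, scale = max(scale, .Machine$double.eps))
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("weibull_fit: shape %.4g, scale %.4g, location %.4g (n = %d, KS = %.3f)\n",
              x$shape, x$scale, x$location, x$n, x$ks))
  invisible(x)
}

#' Quantile function of a fitted Weibull truncated to physical bounds
#'
#' Maps probabilities through the inverse CDF of the fitted distribution
#' restricted to `[bounds[1], bounds[2]]`; used to transform stratified
#' (Latin-hypercube) uniforms into material samples for the second DOE
#' iteration.
#'
#' @param fit a `weibull_fit`.
#' @param p probabilities in (0, 1).
#' @param bounds physical `c(min, max)`; defaults to the bounds stored in the
#'   fit.
#' @return numeric vector of quantiles.
#' @export
quantile_distribution <- function(fit, p, bounds = fit$bounds) {
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  p_lo <- stats::pweibull(max(bounds[1] - fit$location, 0), fit$shape, fit$scale)
  p_hi <- stats::pweibull(bounds[2] - fit$location, fit$shape, fit$scale)
  if (p_hi - p_lo < 1e-3)
    stopf("physical bounds exclude > 99.9%% of the fitted distribution's mass")
  q <- fit$location + stats::qweibull(p_lo + p * (p_hi - p_lo), fit$shape, fit$scale)
  pmin(pmax(q, bounds[1]), bounds[2])
}

#' Sample from a fitted Weibull distribution within physical bounds
#'
#' Inverse-CDF draws; values outside the physical bounds are rejected and
#' redrawn. Errors when the bounds exclude essentially all probability mass
#' (acceptance below 0.1%).
#'
#' @param fit a `weibull_fit`.
#' @param n number of samples.
#' @param bounds physical `c(min, max)`; defaults to the bounds stored in the
#'   fit.
#' @param seed integer seed.
#' @return numeric vector of length `n` with attribute `rejections` (number of
#'   redraws).
#' @export
sample_distribution <- function(fit, n, bounds = fit$bounds, seed = 1L) {
  if (n < 1L) stopf("n must be >= 1")
  p_in <- stats::pweibull(bounds[2] - fit$location, fit$shape, fit$scale) -
    stats::pweibull(max(bounds[1] - fit$location, 0), fit$shape, fit$scale)
  if (p_in < 1e-3)
    stopf("physical bounds exclude > 99.9%% of the fitted distribution's mass")
  with_seed(seed, {
    out <- numeric(0)
    rejections <- 0L
    while (length(out) < n) {
      draw <- fit$location + stats::qweibull(stats::runif(n - length(out)),
                                             fit$shape, fit$scale)
      ok <- draw >= bounds[1] & draw <= bounds[2]
      rejections <- rejections + sum(!ok)
      out <- c(out, draw[ok])
    }
    structure(out[seq_len(n)], rejections = rejections)
  })
}
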