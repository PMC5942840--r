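#' Default design-of-experiments size
#'
#' Central-composite sizing with a fractional factorial core for five or more
#' variables: `2^(k-1) + 2k + 1` for `k >= 5`, `2^k + 2k + 1` below. Five
#' screened variables therefore give the 27-run design used throughout.
#'
#' @param k number of input variables (>= 1).
#' @return integer number of design rows.
#' @export
design_size <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k < 1)
    stopf("k must be a single integer >= 1")
  k <- as.integer(k)
  as.integer(if (k >= 5L) 2^(k - 1L) + 2L * k + 1L else 2^k + 2L * k + 1L)
}

#' Space-filling design over bounded inputs
#'
#' Maximin-optimised Latin hypercube: `restarts` random Latin hypercubes are
#' generated (the first being the plain LHS for the seed) and the design with
#' the largest minimum pairwise distance in the unit cube is kept, then scaled
#' to the variable bounds. Deterministic given the seed.
#'
#' @param bounds named list of `c(min, max)` per variable.
#' @param n_samples number of rows; defaults to [design_size()] of the number
#'   of variables.
#' @param seed integer seed.
#' @param restarts number of random Latin hypercubes scored.
#' @return object of class `doe_design`: list with `samples` (n-by-k matrix),
#'   `bounds`, `method`, `seed`, `min_distance`.
#' @export
sample_design <- function(bounds, n_samples = NULL, seed = 1L, restarts = 100L) {
  k <- length(bounds)
  if (k < 1L || is.null(names(bounds)) || any(!nzchar(names(bounds))))
    stopf("bounds must be a non-empty named list")
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stopf("invalid bounds for '%s': need finite min < max", nm)
  }
  n_samples <- n_samples %||% design_size(k)
  if (n_samples < 2L) stopf("n_samples must be >= 2")
  min_dist <- function(m) min(stats::dist(m))
  best <- with_seed(seed, {
    cand <- lhs::randomLHS(n_samples, k)
    bd <- min_dist(cand)
    for (r in seq_len(max(0L, restarts - 1L))) {
      m <- lhs::randomLHS(n_samples, k)
      d <- min_dist(m)
      if (d > bd) {
        cand <- m
        bd <- d
      }
    }
    list(u = cand, d = bd)
  })
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  samples <- sweep(sweep(best$u, 2L, hi - lo, `*`), 2L, lo, `+`)
  colnames(samples) <- names(bounds)
  structure(list(samples = samples, bounds = bounds,
                 method = sprintf("maximin-LHS (%d restarts)", restarts),
                 seed = as.integer(seed), min_distance = best$d),
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("doe_design: %d runs x %d variables, %s, seed %d, min distance %.4f\n",
              nrow(x$samples), ncol(x$samples), x$method, x$seed, x$min_distance))
  invisible(x)
}

#' Spearman screening of input variables
#'
#' Rank correlation of every input against every landmark output with a
#' two-sided p-value; 95% confidence intervals via the Fisher z-transform with
#' the rank-correlation variance adjustment `1.06 / (n - 3)`. An input is
#' selected when it is significant (`p < alpha`) against at least one output;
#' non-selected inputs are assigned the midpoint of their range for the
#' downstream design stages. A constant input or output column yields an
#' undefined correlation: reported as not selected with a warning.
#'
#' @param design n-by-k matrix/data.frame of inputs (or a `doe_design`).
#' @param responses n-by-m matrix/data.frame of outputs (landmark
#'   displacements).
#' @param bounds named list of ranges used for the frozen midpoints; defaults
#'   to the design bounds when `design` is a `doe_design`.
#' @param alpha significance level (default 0.05).
#' @return object of class `screening`: `table` (data.frame input, output, r,
#'   lo, hi, p), `selected` (named logical), `frozen` (named numeric midpoints
#'   of the non-selected inputs), `alpha`, `n`.
#' @export
screen_variables <- function(design, responses, bounds = NULL, alpha = 0.05) {
  if (inherits(design, "doe_design")) {
    bounds <- bounds %||% design$bounds
    design <- design$samples
  }
  X <- as.matrix(design)
  Y <- as.matrix(responses)
  if (nrow(X) != nrow(Y)) stopf("design and responses disagree on row count")
  if (nrow(X) < 10L) stopf("need at least 10 simulation records to screen")
  n <- nrow(X)
  se <- sqrt(1.06 / (n - 3))
  rows <- list()
  warned <- character(0)
  for (xi in colnames(X)) {
    for (yi in colnames(Y)) {
      x <- X[, xi]; y <- Y[, yi]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(input = xi, output = yi,
                                                r = NA_real_, lo = NA_real_,
                                                hi = NA_real_, p = NA_real_)
        warned <- union(warned, xi)
        next
      }
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      r <- unname(ct$estimate)
      z <- atanh(max(min(r, 1 - 1e-12), -1 + 1e-12))
      # clamp so the interval always contains the estimate (|r| = 1 edge case)
      rows[[length(rows) + 1L]] <- data.frame(
        input = xi, output = yi, r = r,
        lo = min(tanh(z - stats::qnorm(0.975) * se), r),
        hi = max(tanh(z + stats::qnorm(0.975) * se), r),
        p = ct$p.value)
    }
  }
  if (length(warned))
    warning(sprintf("constant column(s) %s: correlation undefined, not selected",
                    paste(warned, collapse = ", ")), call. = FALSE)
  tab <- do.call(rbind, rows)
  selected <- vapply(colnames(X), function(xi) {
    p <- tab$p[tab$input == xi]
    any(!is.na(p) & p < alpha)
  }, logical(1))
  frozen <- numeric(0)
  if (!is.null(bounds)) {
    fz <- setdiff(colnames(X), names(selected)[selected])
    frozen <- vapply(fz, function(nm) {
      b <- bounds[[nm]]
      if (is.null(b)) stats::median(X[, nm]) else mean(b)
    }, numeric(1))
  }
  structure(list(table = tab, selected = selected, frozen = frozen,
                 alpha = alpha, n = n),
            class = "screening")
}

#' @export
print.screening <- function(x, ...) {
  cat(sprintf("screening of %d inputs x %d outputs on n = %d runs (alpha = %g)\n",
              length(x$selected), length(unique(x$table$output)), x$n, x$alpha))
  cat("selected:", paste(names(x$selected)[x$selected], collapse = ", "), "\n")
  if (length(x$frozen))
    cat("frozen at range midpoint:",
        paste(sprintf("%s = %g", names(x$frozen), x$frozen), collapse = ", "), "\n")
  invisible(x)
}

#' Material-property ranges for the uncertain inputs
#'
#' Literature-derived minimum/maximum per material property: bone and
#' cartilage Young's modulus (MPa) and Poisson's ratio, soft-tissue modulus
#' (MPa) and Poisson's ratio, and the viscoelastic scale factor (the
#' 30.5-94.4% relaxation window expressed as a multiplier on the Prony
#' weights).
#'
#' @return named list of `c(min, max)`.
#' @export
material_bounds <- function() {
  list(E_bone = c(5000, 15000), nu_bone = c(0.2, 0.4),
       E_cart = c(0.5, 5), nu_cart = c(0.26, 0.38),
       E_soft = c(0.1, 1), nu_soft = c(0.45, 0.499),
       G_scale = c(0.488, 1.512))
}
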