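# Response-surface surrogates of landmark displacement over the screened
# inputs. Two candidate families are fitted per landmark and the winner is
# chosen by leave-one-out cross-validation: a full quadratic polynomial with
# pairwise interactions, and a Gaussian-process (RBF kernel on bounds-scaled
# inputs, bandwidth by the median heuristic). The loser is kept in an
# ensemble slot with its CV error.

.scale01 <- function(X, bounds) {
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  sweep(sweep(X[, names(bounds), drop = FALSE], 2L, lo, `-`), 2L, hi - lo, `/`)
}

.quad_basis <- function(U) {
  k <- ncol(U)
  cols <- list(intercept = rep(1, nrow(U)))
  for (i in seq_len(k)) cols[[colnames(U)[i]]] <- U[, i]
  for (i in seq_len(k)) cols[[paste0(colnames(U)[i], "^2")]] <- U[, i]^2
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        cols[[paste(colnames(U)[i], colnames(U)[j], sep = ":")]] <- U[, i] * U[, j]
      }
    }
  }
  do.call(cbind, cols)
}

.fit_poly <- function(U, y) {
  M <- .quad_basis(U)
  qr_ <- qr(M)
  if (qr_$rank < ncol(M)) return(NULL) # rank-deficient basis: caller falls back
  beta <- qr.coef(qr_, y)
  H <- diag(M %*% chol2inv(qr.R(qr_)) %*% t(M))
  press <- (y - M %*% beta) / pmax(1 - H, 1e-8)
  list(beta = beta, cv_rmse = sqrt(mean(press^2)))
}

.gp_sigma <- function(U) {
  d2 <- stats::dist(U)^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) m <- 1
  1 / m
}

.fit_gp <- function(U, y, sigma = .gp_sigma(U)) {
  fit <- kernlab::gausspr(x = U, y = y, kernel = "rbfdot",
                          kpar = list(sigma = sigma), var = 2e-3, scaled = FALSE)
  # leave-one-out refits for the CV error
  n <- length(y)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    f <- kernlab::gausspr(x = U[-i, , drop = FALSE], y = y[-i], kernel = "rbfdot",
                          kpar = list(sigma = sigma), var = 2e-3, scaled = FALSE)
    pred[i] <- kernlab::predict(f, U[i, , drop = FALSE])
  }
  list(fit = fit, sigma = sigma, cv_rmse = sqrt(mean((y - pred)^2)))
}

#' Fit response-surface surrogates for the landmark displacements
#'
#' @param design a `doe_design` (or matrix of inputs, in which case `bounds`
#'   must be supplied).
#' @param responses n-by-m matrix/data.frame of landmark displacements with
#'   column names.
#' @param bounds named list of per-variable ranges defining the box the
#'   surrogate is valid on; defaults to the design bounds.
#' @return object of class `facefem_surrogate`: per-output predictors with
#'   their leave-one-out CV RMSE and the candidate-family errors.
#' @export
fit_surrogate <- function(design, responses, bounds = NULL) {
  if (inherits(design, "doe_design")) {
    bounds <- bounds %||% design$bounds
    design <- design$samples
  }
  if (is.null(bounds)) stopf("bounds are required when design is a plain matrix")
  X <- as.matrix(design)
  Y <- as.matrix(responses)
  if (nrow(X) < length(bounds) + 2L)
    stopf("need at least k + 2 design points to fit a surrogate")
  U <- .scale01(X, bounds)
  models <- lapply(colnames(Y), function(nm) {
    y <- Y[, nm]
    if (stats::sd(y) == 0) {
      return(list(kind = "constant", value = y[1], cv_rmse = 0,
                  candidates = c(poly = NA_real_, gp = NA_real_)))
    }
    poly <- .fit_poly(U, y)
    gp <- .fit_gp(U, y)
    cands <- c(poly = if (is.null(poly)) NA_real_ else poly$cv_rmse,
               gp = gp$cv_rmse)
    if (!is.null(poly) && poly$cv_rmse <= gp$cv_rmse) {
      list(kind = "poly", beta = poly$beta, cv_rmse = poly$cv_rmse, candidates = cands)
    } else {
      list(kind = "gp", fit = gp$fit, sigma = gp$sigma, cv_rmse = gp$cv_rmse,
           candidates = cands)
    }
  })
  names(models) <- colnames(Y)
  structure(list(models = models, bounds = bounds, n_train = nrow(X)),
            class = "facefem_surrogate")
}

#' Predict landmark displacements from a fitted surrogate
#'
#' @param object a `facefem_surrogate`.
#' @param newdata matrix/data.frame containing the surrogate's input columns.
#' @param outputs optional subset of output names.
#' @param ... unused.
#' @return numeric matrix, one column per output.
#' @export
predict.facefem_surrogate <- function(object, newdata, outputs = NULL, ...) {
  outputs <- outputs %||% names(object$models)
  X <- as.matrix(as.data.frame(newdata))
  U <- .scale01(X, object$bounds)
  out <- vapply(outputs, function(nm) {
    m <- object$models[[nm]]
    switch(m$kind,
           constant = rep(m$value, nrow(U)),
           poly = as.vector(.quad_basis(U) %*% m$beta),
           gp = as.vector(kernlab::predict(m$fit, U)))
  }, numeric(nrow(U)))
  matrix(out, nrow = nrow(U), dimnames = list(NULL, outputs))
}

#' @export
print.facefem_surrogate <- function(x, ...) {
  cv <- vapply(x$models, `[[`, numeric(1), "cv_rmse")
  kind <- vapply(x$models, `[[`, character(1), "kind")
  print(data.frame(output = names(x$models), family = kind, cv_rmse = cv,
                   row.names = NULL))
  invisible(x)
}
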