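# Multi-objective genetic optimisation (NSGA-II style): non-dominated
# sorting with crowding-distance selection, simulated binary crossover and
# polynomial mutation. The generic minimiser is exposed for verification on
# analytic test problems; optimize_materials() wraps it for the
# match-the-observed-landmarks problem.

# non-dominated sorting; returns integer rank per row (1 = Pareto front)
.nd_sort <- function(F) {
  N <- nrow(F)
  leq <- matrix(TRUE, N, N)
  lt <- matrix(FALSE, N, N)
  for (m in seq_len(ncol(F))) {
    fm <- F[, m]
    cmp <- outer(fm, fm, `<=`)
    leq <- leq & cmp
    lt <- lt | outer(fm, fm, `<`)
  }
  dom <- leq & lt # dom[i, j]: i dominates j
  n_by <- colSums(dom)
  rank <- integer(N)
  cur <- which(n_by == 0L)
  r <- 1L
  remaining <- n_by
  while (length(cur)) {
    rank[cur] <- r
    remaining[cur] <- NA_integer_
    if (length(cur) == 1L) {
      remaining <- remaining - dom[cur, ]
    } else {
      remaining <- remaining - colSums(dom[cur, , drop = FALSE])
    }
    cur <- which(!is.na(remaining) & remaining == 0L)
    r <- r + 1L
  }
  rank
}

.crowding <- function(F, rank) {
  N <- nrow(F)
  cd <- numeric(N)
  for (r in unique(rank)) {
    idx <- which(rank == r)
    if (length(idx) <= 2L) {
      cd[idx] <- Inf
      next
    }
    for (m in seq_len(ncol(F))) {
      o <- idx[order(F[idx, m])]
      rng <- F[o[length(o)], m] - F[o[1L], m]
      cd[o[c(1L, length(o))]] <- Inf
      if (rng > 0) {
        inner <- o[-c(1L, length(o))]
        cd[inner] <- cd[inner] +
          (F[o[-(1:2)], m] - F[o[seq_len(length(o) - 2L)], m]) / rng
      }
    }
  }
  cd
}

.tournament <- function(rank, cd, n) {
  N <- length(rank)
  a <- sample.int(N, n, replace = TRUE)
  b <- sample.int(N, n, replace = TRUE)
  pick_a <- rank[a] < rank[b] | (rank[a] == rank[b] & cd[a] >= cd[b])
  ifelse(pick_a, a, b)
}

.sbx <- function(P1, P2, lower, upper, eta = 15, p_c = 0.9) {
  n <- nrow(P1); k <- ncol(P1)
  C1 <- P1; C2 <- P2
  do_pair <- stats::runif(n) < p_c
  do_gene <- matrix(stats::runif(n * k) < 0.5, n, k) & do_pair
  u <- matrix(stats::runif(n * k), n, k)
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * P1 + (1 - beta) * P2)
  c2 <- 0.5 * ((1 - beta) * P1 + (1 + beta) * P2)
  C1[do_gene] <- c1[do_gene]
  C2[do_gene] <- c2[do_gene]
  lo <- matrix(lower, n, k, byrow = TRUE); hi <- matrix(upper, n, k, byrow = TRUE)
  list(C1 = pmin(pmax(C1, lo), hi), C2 = pmin(pmax(C2, lo), hi))
}

.poly_mutate <- function(X, lower, upper, eta = 20, p_m = NULL) {
  n <- nrow(X); k <- ncol(X)
  p_m <- p_m %||% (1 / k)
  lo <- matrix(lower, n, k, byrow = TRUE); hi <- matrix(upper, n, k, byrow = TRUE)
  span <- hi - lo
  do <- matrix(stats::runif(n * k) < p_m, n, k)
  u <- matrix(stats::runif(n * k), n, k)
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  X[do] <- X[do] + delta[do] * span[do]
  pmin(pmax(X, lo), hi)
}

#' NSGA-II style multi-objective minimiser
#'
#' Evolves a population inside box bounds, stopping early when every
#' objective's population best changes by less than `stability_pct` percent
#' between iterations and at least `pareto_pct` percent of the population is
#' non-dominated.
#'
#' @param fn vectorised objective: takes an n-by-k matrix, returns an n-by-m
#'   matrix of objective values (minimised).
#' @param lower,upper numeric bounds of length k.
#' @param pop_size population size (evaluations per iteration).
#' @param max_gen maximum number of iterations.
#' @param seed integer seed; the run is reproducible given it.
#' @param stability_pct convergence stability threshold (percent).
#' @param pareto_pct required non-dominated fraction (percent).
#' @param eta_c,eta_m SBX and mutation distribution indices.
#' @param goal_frac fraction of the next population reserved for goal-driven
#'   elites: candidates with the smallest equally weighted sum of
#'   range-normalised objectives. This is the "goal driven" ingredient that
#'   keeps selection pressure towards the aggregate goal when many points are
#'   mutually non-dominated; `0` gives plain NSGA-II selection.
#' @return list with `X` (final population), `F` (objectives), `rank`
#'   (non-domination rank), `generations`, `converged`.
#' @export
nsga2_minimize <- function(fn, lower, upper, pop_size = 100L, max_gen = 10L,
                           seed = 1L, stability_pct = 2, pareto_pct = 70,
                           eta_c = 15, eta_m = 20, goal_frac = 0.1) {
  k <- length(lower)
  if (length(upper) != k || any(upper <= lower)) stopf("invalid bounds")
  scalar_score <- function(F) {
    rng <- apply(F, 2L, function(x) max(diff(range(x)), 1e-12))
    rowMeans(sweep(sweep(F, 2L, apply(F, 2L, min), `-`), 2L, rng, `/`))
  }
  with_seed(seed, {
    U <- lhs::randomLHS(pop_size, k)
    X <- sweep(sweep(U, 2L, upper - lower, `*`), 2L, lower, `+`)
    F <- fn(X)
    rank <- .nd_sort(F)
    cd <- .crowding(F, rank)
    best_prev <- apply(F, 2L, min)
    converged <- FALSE
    gen <- 0L
    for (gen in seq_len(max_gen)) {
      i1 <- .tournament(rank, cd, pop_size)
      i2 <- .tournament(rank, cd, pop_size)
      half <- ceiling(pop_size / 2)
      off <- .sbx(X[i1[seq_len(half)], , drop = FALSE],
                  X[i2[seq_len(half)], , drop = FALSE], lower, upper, eta = eta_c)
      Xo <- rbind(off$C1, off$C2)[seq_len(pop_size), , drop = FALSE]
      Xo <- .poly_mutate(Xo, lower, upper, eta = eta_m)
      Fo <- fn(Xo)
      Xc <- rbind(X, Xo)
      Fc <- rbind(F, Fo)
      rc <- .nd_sort(Fc)
      cc <- .crowding(Fc, rc)
      n_el <- round(goal_frac * pop_size)
      if (n_el > 0L) {
        el <- order(rc, scalar_score(Fc))[seq_len(n_el)]
        keep <- c(el, setdiff(order(rc, -cc), el)[seq_len(pop_size - n_el)])
      } else {
        keep <- order(rc, -cc)[seq_len(pop_size)]
      }
      X <- Xc[keep, , drop = FALSE]
      F <- Fc[keep, , drop = FALSE]
      rank <- .nd_sort(F)
      cd <- .crowding(F, rank)
      best <- apply(F, 2L, min)
      stable <- all(abs(best - best_prev) <=
                      (stability_pct / 100) * pmax(abs(best_prev), 1e-12))
      nd_frac <- mean(rank == 1L)
      best_prev <- best
      if (stable && nd_frac >= pareto_pct / 100) {
        converged <- TRUE
        break
      }
    }
    list(X = X, F = F, rank = rank, generations = gen, converged = converged)
  })
}

#' Optimisation targets for the landmark-matching problem
#'
#' The lower lip (LL) is always excluded: the mandibular osteotomy that
#' drives it is not modelled, so its target is not meaningful.
#'
#' @param targets named numeric of observed landmark displacements (mm).
#' @param include landmarks to optimise on; defaults to N, UL, RC, LC.
#' @return object of class `optimization_targets`.
#' @export
optimization_targets <- function(targets, include = c("N", "UL", "RC", "LC")) {
  if ("LL" %in% include) stopf("LL is excluded from optimisation (mandible not modelled)")
  if (!all(include %in% names(targets)))
    stopf("targets missing for: %s",
          paste(setdiff(include, names(targets)), collapse = ", "))
  structure(list(targets = targets[include], include = include),
            class = "optimization_targets")
}

#' Default MOGA configuration
#'
#' @param population evaluations per iteration.
#' @param max_iterations iteration cap.
#' @param stability_pct convergence stability (percent change of per-objective
#'   bests between iterations).
#' @param pareto_pct required non-dominated fraction of the population
#'   (percent).
#' @param n_extract number of best candidates extracted.
#' @param goal_frac goal-elite fraction of the population, see
#'   [nsga2_minimize()].
#' @return a list.
#' @export
moga_config <- function(population = 1000L, max_iterations = 10L,
                        stability_pct = 2, pareto_pct = 70, n_extract = 100L,
                        goal_frac = 0.1) {
  if (population < n_extract)
    stopf("population (%d) must be at least n_extract (%d)", population, n_extract)
  list(population = as.integer(population), max_iterations = as.integer(max_iterations),
       stability_pct = stability_pct, pareto_pct = pareto_pct,
       n_extract = as.integer(n_extract), goal_frac = goal_frac)
}

#' Optimise material properties against observed landmark displacements
#'
#' Minimises, for each included landmark, the absolute difference between the
#' surrogate prediction and the observed target: when the target is reachable
#' the objectives pull candidates onto it, when it lies outside the achievable
#' range the same objectives drive candidates to the bound that gets closest
#' (minimise/maximise fallback). The final population is non-dominated sorted;
#' candidates are scored by the equally weighted sum of range-normalised
#' objectives, and the best `n_extract` (front by front) are returned. As a
#' final goal-driven exploitation step the top-scoring candidate is polished
#' by bounded quasi-Newton descent of the weighted squared goal mismatch on
#' the surrogates (surrogate evaluations only); the polished point joins the
#' candidate set and the ranking is recomputed.
#'
#' @param surrogates a `facefem_surrogate` covering the included landmarks.
#' @param targets an [optimization_targets()].
#' @param bounds named list of ranges for the free (material) variables.
#' @param fixed named numeric of surrogate inputs held constant during the
#'   optimisation (e.g. the advancement fixed at the subject's planned value).
#' @param config a [moga_config()].
#' @param seed integer seed.
#' @param scales optional named numeric, one value per included landmark: the
#'   normalisation scale of each objective in the equally weighted score
#'   (typically that landmark's DOE response range). Without it the achieved
#'   objective range over the final population is used, which over-weights
#'   landmarks the materials can barely move.
#' @return object of class `pareto_candidates`: `X` (n_extract-by-k matrix of
#'   inputs), `objectives`, `rank`, `score`, plus the run metadata.
#' @export
optimize_materials <- function(surrogates, targets, bounds, fixed = numeric(0),
                               config = moga_config(), seed = 1L,
                               scales = NULL) {
  if (!inherits(targets, "optimization_targets")) stopf("targets must be optimization_targets")
  vars <- names(bounds)
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  inc <- targets$include
  tg <- targets$targets
  fn <- function(X) {
    nd <- as.data.frame(X)
    names(nd) <- vars
    for (nm in names(fixed)) nd[[nm]] <- fixed[[nm]]
    P <- predict(surrogates, nd, outputs = inc)
    abs(sweep(P, 2L, tg, `-`))
  }
  res <- nsga2_minimize(fn, lower, upper, pop_size = config$population,
                        max_gen = config$max_iterations, seed = seed,
                        stability_pct = config$stability_pct,
                        pareto_pct = config$pareto_pct,
                        goal_frac = config$goal_frac %||% 0.1)
  dup <- duplicated(res$X)
  X <- res$X[!dup, , drop = FALSE]
  F <- res$F[!dup, , drop = FALSE]
  rank <- res$rank[!dup]
  rng <- if (!is.null(scales)) {
    if (!all(inc %in% names(scales))) stopf("scales must cover every included landmark")
    pmax(as.numeric(scales[inc]), 1e-12)
  } else {
    apply(F, 2L, function(x) {
      d <- diff(range(x))
      if (d > 0) d else 1
    })
  }
  # goal-driven polish of the best aggregate candidate (surrogate-only)
  w <- 1 / rng
  sq_goal <- function(x) {
    X1 <- matrix(x, 1L)
    colnames(X1) <- vars
    sum((w * fn(X1)[1L, ])^2)
  }
  x0 <- X[order(rank, rowMeans(sweep(sweep(F, 2L, apply(F, 2L, min), `-`), 2L, rng, `/`)))[1L], ]
  pol <- tryCatch(stats::optim(x0, sq_goal, method = "L-BFGS-B",
                               lower = lower, upper = upper),
                  error = function(e) NULL)
  if (!is.null(pol)) {
    Xp <- matrix(pol$par, 1L, dimnames = list(NULL, vars))
    X <- rbind(X, Xp)
    F <- rbind(F, fn(Xp))
    rank <- .nd_sort(F)
  }
  score <- rowMeans(sweep(sweep(F, 2L, apply(F, 2L, min), `-`), 2L, rng, `/`))
  o <- order(rank, score)
  take <- o[seq_len(min(config$n_extract, length(o)))]
  if (length(take) < config$n_extract)
    warning(sprintf("only %d distinct candidates available (requested %d)",
                    length(take), config$n_extract), call. = FALSE)
  colnames(X) <- vars
  structure(list(X = X[take, , drop = FALSE],
                 objectives = F[take, , drop = FALSE],
                 rank = rank[take], score = score[take],
                 included = inc, targets = tg, fixed = fixed, bounds = bounds,
                 generations = res$generations, converged = res$converged,
                 seed = as.integer(seed)),
            class = "pareto_candidates")
}

#' @export
print.pareto_candidates <- function(x, ...) {
  cat(sprintf("pareto_candidates: %d candidates x %d inputs (%s), %d generations%s\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", "),
              x$generations, if (x$converged) ", converged" else ""))
  cat(sprintf("ranks: %s\n", paste(names(table(x$rank)), table(x$rank),
                                   sep = "x", collapse = ", ")))
  invisible(x)
}
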