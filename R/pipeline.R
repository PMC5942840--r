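# Two-iteration probabilistic pipeline over synthetic subjects:
# screen -> DOE I -> optimisation on training subjects -> Weibull fitting ->
# DOE II on validation subjects -> validation -> report.
# Every stage consumes and produces files under the run directory, so stages
# can be rerun independently; FEM response tables are cached on disk keyed by
# a content hash of their inputs.

#' Pipeline configuration
#'
#' Collects the phantom geometry, material bounds, Prony defaults, design
#' sizes, MOGA preset, subject split and per-stage seeds. The `full` preset
#' uses the full MOGA population (1000) and 30 time steps; the `desk` preset
#' halves the population and uses a shorter time grid so a complete run fits
#' on a single desktop core in minutes.
#'
#' @param preset `"desk"` or `"full"`.
#' @param seed base integer seed; per-stage seeds are derived from it.
#' @param outdir run directory (created when missing).
#' @param geometry a [phantom_geometry()].
#' @param bounds material bounds, see [material_bounds()].
#' @param prony a [prony_series()].
#' @param adv_tol advancement uncertainty (mm, the +-2 mm execution window).
#' @param screening_n runs in the screening design.
#' @param doe1_n,doe2_n runs per subject in DOE I / DOE II; `NULL` means
#'   [design_size()] of the number of screened variables.
#' @param moga a [moga_config()]; `NULL` picks the preset default.
#' @param n_steps,t_end,ramp time-integration protocol.
#' @param noise_sd landmark measurement noise of the synthetic truth (mm).
#' @param truth_sd_frac between-subject spread of the true material
#'   properties, as a fraction of each Table-range width.
#' @param exec_sd standard deviation (mm) of the surgical execution error on
#'   the advancement, truncated at `adv_tol`.
#' @param training,validation subject splits (disjoint).
#' @param screen_subject subject used for the variable screen.
#' @param selected character vector fixing the screened-in variable set (the
#'   correlation table is still computed and written). The default is the
#'   canonical five-variable set (cartilage stiffness, soft-tissue stiffness
#'   and Poisson's ratio, viscoelastic scale, advancement), mirroring how a
#'   single subject's screening is carried across the cohort; `NULL` lets the
#'   significance rule decide from the phantom's own screen.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("desk", "full"), seed = 1L,
                            outdir = file.path(tempdir(), "facefem_run"),
                            geometry = NULL, bounds = material_bounds(),
                            prony = prony_series(), adv_tol = 2,
                            screening_n = NULL, doe1_n = NULL, doe2_n = NULL,
                            moga = NULL, n_steps = NULL, t_end = 60, ramp = 1,
                            noise_sd = 0.2, truth_sd_frac = 0.1, exec_sd = 1,
                            training = c("P2", "P3", "P5", "P7", "P8"),
                            validation = c("P1", "P4", "P6"),
                            screen_subject = "P1",
                            selected = c("E_cart", "E_soft", "nu_soft",
                                         "G_scale", "x_adv")) {
  preset <- match.arg(preset)
  desk <- preset == "desk"
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    outdir = outdir,
    geometry = geometry %||% phantom_geometry(),
    bounds = bounds,
    prony = prony,
    adv_tol = adv_tol,
    screening_n = screening_n %||% (if (desk) 60L else 100L),
    doe1_n = doe1_n,
    doe2_n = doe2_n,
    moga = moga %||% (if (desk) moga_config(population = 500L) else moga_config()),
    n_steps = n_steps %||% (if (desk) 12L else 30L),
    t_end = t_end, ramp = ramp,
    noise_sd = noise_sd, truth_sd_frac = truth_sd_frac, exec_sd = exec_sd,
    training = training, validation = validation,
    screen_subject = screen_subject, selected = selected)
  if (length(intersect(training, validation)))
    stopf("training and validation subject sets must be disjoint")
  if (!screen_subject %in% c(training, validation))
    stopf("screen_subject must be one of the subjects")
  cfg$seeds <- list(truth = .stage_seed(seed, 11L), screen = .stage_seed(seed, 13L),
                    doe1 = .stage_seed(seed, 17L), moga = .stage_seed(seed, 23L),
                    doe2 = .stage_seed(seed, 29L))
  structure(cfg, class = "pipeline_config")
}

.stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("pipeline_config (%s preset), seed %d, outdir %s\n",
              x$preset, x$seed, x$outdir))
  cat(sprintf("  screening n = %d, MOGA population = %d, time steps = %d\n",
              x$screening_n, x$moga$population, x$n_steps))
  cat(sprintf("  training: %s | validation: %s\n",
              paste(x$training, collapse = ","), paste(x$validation, collapse = ",")))
  invisible(x)
}

# shared per-config solver setup, memoised (mesh + system + bc + time grid)
.cfg_ctx <- function(config) {
  key <- hash_object(list(config$geometry, config$ramp, config$t_end, config$n_steps))
  if (!is.null(.facefem_env$cfg_ctx) && identical(.facefem_env$cfg_ctx$key, key))
    return(.facefem_env$cfg_ctx)
  ph <- build_phantom(config$geometry, seed = config$seed)
  ctx <- list(key = key, mesh = ph$mesh, landmarks = ph$landmarks,
              sys = fem_system(ph$mesh),
              bc = default_boundary_spec(ph$mesh, ramp = config$ramp,
                                         hold = config$t_end - config$ramp),
              time_grid = make_time_grid(config$ramp, config$t_end, config$n_steps))
  .facefem_env$cfg_ctx <- ctx
  ctx
}

.log_stage <- function(config, stage, info = list()) {
  path <- file.path(config$outdir, "log.jsonl")
  rec <- c(list(stage = stage, seed = config$seed,
                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), info)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = path, append = TRUE)
}

# full input vector from a design row: design columns override the frozen /
# default midpoint values
.full_inputs <- function(row, frozen, bounds) {
  mids <- vapply(bounds, mean, numeric(1))
  iv <- c(mids, x_adv = NA_real_)
  iv[names(frozen)] <- frozen
  iv[names(row)] <- as.numeric(row)
  iv
}

# FEM responses for a table of input rows, cached on disk
.run_fem_table <- function(config, inputs_df, prefix) {
  ctx <- .cfg_ctx(config)
  key <- hash_object(list(inputs_df, config$geometry, config$ramp, config$t_end,
                          config$n_steps, config$prony))
  key_file <- paste0(prefix, ".key")
  resp_file <- paste0(prefix, "_responses.csv")
  if (file.exists(key_file) && file.exists(resp_file) &&
      identical(readLines(key_file, warn = FALSE)[1], key)) {
    return(as.matrix(utils::read.csv(resp_file)))
  }
  Y <- matrix(NA_real_, nrow(inputs_df), 5L,
              dimnames = list(NULL, c("N", "UL", "LL", "RC", "LC")))
  for (i in seq_len(nrow(inputs_df))) {
    iv <- do.call(input_vector,
                  c(as.list(inputs_df[i, , drop = FALSE]), list(prony = config$prony)))
    field <- tryCatch(
      solve_viscoelastic(ctx$mesh, ctx$bc, iv, prony = config$prony,
                         time_grid = ctx$time_grid, system = ctx$sys),
      error = function(e) stopf("FEM solve failed at design row %d (%s): %s", i,
                                paste(sprintf("%s=%.4g", names(inputs_df),
                                              as.numeric(inputs_df[i, ])),
                                      collapse = ", "),
                                conditionMessage(e)))
    Y[i, ] <- extract_landmarks(field, ctx$landmarks)
  }
  utils::write.csv(as.data.frame(Y), resp_file, row.names = FALSE)
  writeLines(key, key_file)
  Y
}

#' Generate the synthetic subject cohort and its ground truth
#'
#' Builds the phantom, draws per-subject hidden true material properties
#' (population spread around the range midpoints) and achieved advancements
#' (planned value from the packaged cohort table plus a truncated-normal
#' execution error), runs the forward solve per subject and writes the
#' phantom artifacts (`mesh.msh`, `mesh.vtu`, `landmarks.json`) and the
#' subject table (`subjects.csv`) to the run directory.
#'
#' @param config a [pipeline_config()].
#' @return the subject data.frame, invisibly.
#' @export
stage_phantom <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  ctx <- .cfg_ctx(config)
  validate_phantom(ctx$mesh, ctx$landmarks)
  write_msh(ctx$mesh, file.path(config$outdir, "mesh.msh"))
  write_vtu(ctx$mesh, file.path(config$outdir, "mesh.vtu"))
  write_landmarks_json(ctx$landmarks, file.path(config$outdir, "landmarks.json"))
  cohort <- load_cohort_table()
  mat_names <- names(config$bounds)
  subj <- with_seed(config$seeds$truth, {
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      id <- cohort$patient[i]
      planned <- cohort$planned_advancement_mm[i]
      tm <- vapply(mat_names, function(nm) {
        b <- config$bounds[[nm]]
        repeat {
          v <- stats::rnorm(1, mean(b), config$truth_sd_frac * diff(b))
          if (v >= b[1] && v <= b[2]) return(v)
        }
      }, numeric(1))
      repeat {
        err <- stats::rnorm(1, 0, config$exec_sd)
        if (abs(err) <= config$adv_tol) break
      }
      data.frame(patient = id,
                 role = if (id %in% config$training) "training" else "validation",
                 planned_adv = planned, x_true = planned + err,
                 as.list(tm))
    })
    do.call(rbind, rows)
  })
  obs <- matrix(NA_real_, nrow(subj), 5L,
                dimnames = list(NULL, paste0("obs_", c("N", "UL", "LL", "RC", "LC"))))
  for (i in seq_len(nrow(subj))) {
    iv <- do.call(input_vector,
                  c(as.list(subj[i, names(config$bounds)]),
                    list(x_adv = subj$x_true[i], prony = config$prony)))
    obs[i, ] <- synthesize_truth(ctx$mesh, ctx$landmarks, iv,
                                 noise_sd = config$noise_sd,
                                 seed = .stage_seed(config$seeds$truth, i),
                                 bc = ctx$bc, prony = config$prony,
                                 time_grid = ctx$time_grid, system = ctx$sys)
  }
  subj <- cbind(subj, as.data.frame(obs))
  utils::write.csv(subj, file.path(config$outdir, "subjects.csv"), row.names = FALSE)
  .log_stage(config, "phantom", list(n_subjects = nrow(subj)))
  invisible(subj)
}

.read_subjects <- function(config) {
  f <- file.path(config$outdir, "subjects.csv")
  if (!file.exists(f)) stopf("run directory lacks subjects.csv: run stage_phantom first")
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Variable screening stage
#'
#' Runs a space-filling design over all eight uncertain inputs on the
#' screening subject and applies the Spearman selection rule; the surviving
#' inputs enter the later designs as ranges, the rest are frozen at their
#' range midpoints. Writes `screen_design.csv`, `screen_responses.csv`,
#' `correlation_table.csv` and `screening.json`.
#'
#' @param config a [pipeline_config()].
#' @return the `screening` object, invisibly.
#' @export
stage_screen <- function(config) {
  subj <- .read_subjects(config)
  s <- subj[subj$patient == config$screen_subject, ]
  bounds <- c(config$bounds,
              list(x_adv = c(s$planned_adv - config$adv_tol,
                             s$planned_adv + config$adv_tol)))
  des <- sample_design(bounds, n_samples = config$screening_n,
                       seed = config$seeds$screen)
  utils::write.csv(as.data.frame(des$samples),
                   file.path(config$outdir, "screen_design.csv"), row.names = FALSE)
  Y <- .run_fem_table(config, as.data.frame(des$samples),
                      file.path(config$outdir, "screen"))
  scr <- screen_variables(des, Y)
  utils::write.csv(scr$table, file.path(config$outdir, "correlation_table.csv"),
                   row.names = FALSE)
  sel_names <- names(scr$selected)[scr$selected]
  frozen <- scr$frozen
  if (!is.null(config$selected)) {
    bad <- setdiff(config$selected, names(bounds))
    if (length(bad)) stopf("unknown variables in config$selected: %s",
                           paste(bad, collapse = ", "))
    sel_names <- config$selected
    fz <- setdiff(names(bounds), sel_names)
    frozen <- vapply(fz, function(nm) mean(bounds[[nm]]), numeric(1))
  }
  jsonlite::write_json(list(selected = sel_names,
                            frozen = as.list(frozen),
                            alpha = scr$alpha, n = scr$n),
                       file.path(config$outdir, "screening.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_stage(config, "screen",
             list(selected = paste(names(scr$selected)[scr$selected], collapse = ",")))
  invisible(scr)
}

.read_screening <- function(config) {
  f <- file.path(config$outdir, "screening.json")
  if (!file.exists(f)) stopf("run directory lacks screening.json: run stage_screen first")
  jsonlite::read_json(f, simplifyVector = TRUE)
}

.subject_bounds <- function(config, scr, planned) {
  sel <- scr$selected
  bounds <- config$bounds[intersect(names(config$bounds), sel)]
  if ("x_adv" %in% sel)
    bounds$x_adv <- c(planned - config$adv_tol, planned + config$adv_tol)
  bounds
}

#' First design-of-experiments iteration (uniform ranges)
#'
#' For every subject: a maximin-LHS design over the screened inputs with
#' uniform literature ranges (the advancement centred on the subject's
#' planned value), one forward solve per row, and per-landmark min/max
#' prediction ranges. Writes `doe1_<id>_design.csv`,
#' `doe1_<id>_responses.csv` and `doe1_ranges.json`.
#'
#' @param config a [pipeline_config()].
#' @return named list of per-subject range lists, invisibly.
#' @export
stage_doe1 <- function(config) {
  subj <- .read_subjects(config)
  scr <- .read_screening(config)
  frozen <- unlist(scr$frozen)
  ranges <- list()
  for (i in seq_len(nrow(subj))) {
    id <- subj$patient[i]
    bounds <- .subject_bounds(config, scr, subj$planned_adv[i])
    n <- config$doe1_n %||% design_size(length(bounds))
    des <- sample_design(bounds, n_samples = n,
                         seed = .stage_seed(config$seeds$doe1, i))
    X <- as.data.frame(des$samples)
    utils::write.csv(X, file.path(config$outdir, sprintf("doe1_%s_design.csv", id)),
                     row.names = FALSE)
    full <- as.data.frame(t(apply(X, 1L, .full_inputs, frozen = frozen,
                                  bounds = config$bounds)))
    full$x_adv[is.na(full$x_adv)] <- subj$planned_adv[i]
    Y <- .run_fem_table(config, full,
                        file.path(config$outdir, sprintf("doe1_%s", id)))
    ranges[[id]] <- lapply(as.data.frame(Y), range)
  }
  jsonlite::write_json(ranges, file.path(config$outdir, "doe1_ranges.json"),
                       digits = NA, pretty = TRUE)
  .log_stage(config, "doe1", list(n_subjects = nrow(subj)))
  invisible(ranges)
}

#' Material-property optimisation on the training subjects
#'
#' Fits the response-surface surrogates on each training subject's DOE I
#' results and runs the goal-driven multi-objective optimisation against the
#' subject's observed landmark displacements (N, UL, RC, LC; LL excluded),
#' with the advancement fixed at the planned value. Writes
#' `candidates_<id>.csv` (inputs plus achieved objectives).
#'
#' @param config a [pipeline_config()].
#' @return named list of `pareto_candidates`, invisibly.
#' @export
stage_optimize <- function(config) {
  subj <- .read_subjects(config)
  scr <- .read_screening(config)
  out <- list()
  for (i in which(subj$patient %in% config$training)) {
    id <- subj$patient[i]
    des_f <- file.path(config$outdir, sprintf("doe1_%s_design.csv", id))
    resp_f <- file.path(config$outdir, sprintf("doe1_%s_responses.csv", id))
    if (!file.exists(des_f) || !file.exists(resp_f))
      stopf("missing DOE I results for %s: run stage_doe1 first", id)
    X <- utils::read.csv(des_f)
    Y <- as.matrix(utils::read.csv(resp_f))
    bounds <- .subject_bounds(config, scr, subj$planned_adv[i])
    sur <- fit_surrogate(as.matrix(X), Y, bounds = bounds)
    mat_vars <- setdiff(names(bounds), "x_adv")
    if (length(mat_vars) == 0L) stopf("no material variables were screened in")
    tg <- optimization_targets(stats::setNames(
      as.numeric(subj[i, paste0("obs_", c("N", "UL", "RC", "LC"))]),
      c("N", "UL", "RC", "LC")))
    scales <- apply(Y[, c("N", "UL", "RC", "LC"), drop = FALSE], 2L,
                    function(x) diff(range(x)))
    # the advancement is a free optimisation variable (the optimiser infers
    # the achieved advancement from the observed landmarks); only the
    # material columns enter the candidate matrix
    pc <- optimize_materials(sur, tg, bounds,
                             config = config$moga,
                             seed = .stage_seed(config$seeds$moga, i),
                             scales = scales)
    df <- cbind(as.data.frame(pc$X[, mat_vars, drop = FALSE]),
                stats::setNames(as.data.frame(pc$objectives),
                                paste0("obj_", colnames(pc$objectives))),
                rank = pc$rank)
    utils::write.csv(df, file.path(config$outdir, sprintf("candidates_%s.csv", id)),
                     row.names = FALSE)
    out[[id]] <- pc
  }
  .log_stage(config, "optimize", list(subjects = paste(names(out), collapse = ",")))
  invisible(out)
}

#' Weibull fitting of the pooled optimised candidates
#'
#' Row-wise superimposition of the training subjects' candidate matrices and
#' a location-shifted Weibull fit per material parameter. Writes
#' `pooled_candidates.csv` and `weibull_fits.json`.
#'
#' @param config a [pipeline_config()].
#' @return named list of `weibull_fit`, invisibly.
#' @export
stage_fitdist <- function(config) {
  files <- file.path(config$outdir, sprintf("candidates_%s.csv", config$training))
  if (!all(file.exists(files)))
    stopf("missing candidate files for: %s",
          paste(config$training[!file.exists(files)], collapse = ", "))
  sets <- lapply(files, function(f) {
    df <- utils::read.csv(f)
    as.matrix(df[, !grepl("^obj_|^rank$", names(df)), drop = FALSE])
  })
  pooled <- pool_candidates(sets)
  utils::write.csv(as.data.frame(pooled),
                   file.path(config$outdir, "pooled_candidates.csv"),
                   row.names = FALSE)
  fits <- lapply(colnames(pooled), function(nm)
    fit_weibull(pooled[, nm], bounds = config$bounds[[nm]]))
  names(fits) <- colnames(pooled)
  jsonlite::write_json(lapply(fits, function(f)
    list(shape = f$shape, scale = f$scale, location = f$location,
         n = f$n, ks = f$ks, bounds = f$bounds)),
    file.path(config$outdir, "weibull_fits.json"), digits = NA, pretty = TRUE)
  .log_stage(config, "fitdist", list(parameters = paste(names(fits), collapse = ",")))
  invisible(fits)
}

.read_weibull_fits <- function(config) {
  f <- file.path(config$outdir, "weibull_fits.json")
  if (!file.exists(f)) stopf("run directory lacks weibull_fits.json: run stage_fitdist first")
  lst <- jsonlite::read_json(f, simplifyVector = TRUE)
  lapply(lst, function(l) structure(l, class = "weibull_fit"))
}

#' Second design-of-experiments iteration (fitted distributions)
#'
#' For every validation subject the same space-filling DOE machinery as the
#' first iteration is used, with the uniform material ranges replaced by the
#' fitted Weibull distributions: a maximin Latin hypercube in probability
#' space is mapped through each material's truncated inverse CDF (bounded by
#' the physical ranges), while the advancement stays uniform over planned +-
#' `adv_tol`. One forward solve per sample, then per-landmark prediction
#' envelopes with truth containment. Also writes the midline skin profile
#' band and the extreme (min/max) displacement fields as VTU.
#'
#' @param config a [pipeline_config()].
#' @return named list of `prediction_envelope_set`, invisibly.
#' @export
stage_doe2 <- function(config) {
  subj <- .read_subjects(config)
  scr <- .read_screening(config)
  fits <- .read_weibull_fits(config)
  ctx <- .cfg_ctx(config)
  frozen <- unlist(scr$frozen)
  out <- list()
  for (i in which(subj$patient %in% config$validation)) {
    id <- subj$patient[i]
    bounds <- .subject_bounds(config, scr, subj$planned_adv[i])
    n <- config$doe2_n %||% design_size(length(bounds))
    sseed <- .stage_seed(config$seeds$doe2, i)
    # stratified probability design: materials map through the truncated
    # inverse CDF of their fitted distribution, the advancement stays uniform.
    # When the run counts match, the DOE I probability design is reused
    # (matched designs), so the two iterations differ only by the input
    # distributions, not by the sampling realisation.
    pcols <- names(fits)
    if ("x_adv" %in% scr$selected) pcols <- c(pcols, "x_adv")
    d1_file <- file.path(config$outdir, sprintf("doe1_%s_design.csv", id))
    U <- NULL
    if (file.exists(d1_file)) {
      d1 <- utils::read.csv(d1_file)
      if (nrow(d1) == n && all(pcols %in% names(d1))) {
        U <- vapply(pcols, function(nm) {
          b <- bounds[[nm]]
          (d1[[nm]] - b[1]) / diff(b)
        }, numeric(n))
      }
    }
    if (is.null(U)) {
      U <- sample_design(stats::setNames(rep(list(c(0, 1)), length(pcols)), pcols),
                         n_samples = n, seed = sseed)$samples
    }
    X <- as.data.frame(lapply(names(fits), function(nm)
      quantile_distribution(fits[[nm]], U[, nm])))
    names(X) <- names(fits)
    if ("x_adv" %in% scr$selected) {
      X$x_adv <- subj$planned_adv[i] - config$adv_tol +
        U[, "x_adv"] * 2 * config$adv_tol
    }
    utils::write.csv(X, file.path(config$outdir, sprintf("doe2_%s_design.csv", id)),
                     row.names = FALSE)
    full <- as.data.frame(t(apply(X, 1L, .full_inputs, frozen = frozen,
                                  bounds = config$bounds)))
    full$x_adv[is.na(full$x_adv)] <- subj$planned_adv[i]
    Y <- .run_fem_table(config, full,
                        file.path(config$outdir, sprintf("doe2_%s", id)))
    truths <- stats::setNames(as.numeric(subj[i, paste0("obs_", c("N", "UL", "LL", "RC", "LC"))]),
                              c("N", "UL", "LL", "RC", "LC"))
    out[[id]] <- build_envelope(Y, truths)
    .write_doe2_extras(config, ctx, full, Y, id)
  }
  jsonlite::write_json(lapply(out, function(e)
    lapply(e$landmarks, function(l) l[c("min", "max", "breaks", "counts",
                                        "cdf_x", "cdf_p", "truth", "contains_truth")])),
    file.path(config$outdir, "envelopes.json"), digits = NA, pretty = TRUE)
  .log_stage(config, "doe2", list(subjects = paste(names(out), collapse = ",")))
  invisible(out)
}

# midline profile band and extreme displacement fields for one subject
.write_doe2_extras <- function(config, ctx, full, Y, id) {
  mesh <- ctx$mesh
  skin <- mesh$node_sets[["soft_tissue.y_max"]]
  mid <- skin[abs(mesh$nodes[skin, 1]) < 1e-8]
  mid <- mid[order(mesh$nodes[mid, 3])]
  mean_disp <- rowMeans(Y)
  i_min <- which.min(mean_disp)
  i_max <- which.max(mean_disp)
  band <- NULL
  for (ix in c(i_min, i_max)) {
    iv <- do.call(input_vector, c(as.list(full[ix, , drop = FALSE]),
                                  list(prony = config$prony)))
    field <- solve_viscoelastic(mesh, ctx$bc, iv, prony = config$prony,
                                time_grid = ctx$time_grid, system = ctx$sys)
    u <- field$U[, ncol(field$U)]
    uy <- u[3L * (mid - 1L) + 2L]
    band <- if (is.null(band)) cbind(lo = uy, hi = uy)
            else cbind(lo = pmin(band[, "lo"], uy), hi = pmax(band[, "hi"], uy))
    U3 <- matrix(u, ncol = 3L, byrow = TRUE)
    write_vtu(mesh, file.path(config$outdir,
                              sprintf("field_%s_%s.vtu", id,
                                      if (ix == i_min) "min" else "max")),
              point_data = list(displacement = U3))
  }
  utils::write.csv(data.frame(z = mesh$nodes[mid, 3], y_lo = band[, "lo"],
                              y_hi = band[, "hi"]),
                   file.path(config$outdir, sprintf("midline_%s.csv", id)),
                   row.names = FALSE)
}

#' Validation stage: truth containment and range refinement
#'
#' Compares every validation subject's DOE II envelopes against the observed
#' displacements and the DOE I ranges. Writes `validation.csv` and
#' `validation.json`.
#'
#' @param config a [pipeline_config()].
#' @return the validation data.frame, invisibly.
#' @export
stage_validate <- function(config) {
  subj <- .read_subjects(config)
  env_f <- file.path(config$outdir, "envelopes.json")
  rng_f <- file.path(config$outdir, "doe1_ranges.json")
  if (!file.exists(env_f)) stopf("run directory lacks envelopes.json: run stage_doe2 first")
  if (!file.exists(rng_f)) stopf("run directory lacks doe1_ranges.json: run stage_doe1 first")
  envs <- jsonlite::read_json(env_f, simplifyVector = TRUE)
  rngs <- jsonlite::read_json(rng_f, simplifyVector = TRUE)
  rows <- list()
  for (id in names(envs)) {
    i <- match(id, subj$patient)
    truths <- stats::setNames(as.numeric(subj[i, paste0("obs_", c("N", "UL", "LL", "RC", "LC"))]),
                              c("N", "UL", "LL", "RC", "LC"))
    eset <- structure(list(landmarks = envs[[id]], n_runs = NA_integer_),
                      class = "prediction_envelope_set")
    v <- validate_envelopes(eset, truths,
                            doe1_ranges = lapply(rngs[[id]], as.numeric))
    v <- cbind(patient = id, v)
    rows[[id]] <- v
  }
  val <- do.call(rbind, rows)
  utils::write.csv(val, file.path(config$outdir, "validation.csv"), row.names = FALSE)
  jsonlite::write_json(val, file.path(config$outdir, "validation.json"),
                       digits = NA, pretty = TRUE, dataframe = "rows")
  .log_stage(config, "validate", list(n = nrow(val)))
  invisible(val)
}

#' Run the complete two-iteration pipeline
#'
#' Executes phantom, screen, DOE I, optimisation, distribution fitting,
#' DOE II, validation and reporting in order.
#'
#' @param config a [pipeline_config()].
#' @return list with the subjects table, screening, DOE I ranges, Weibull
#'   fits, envelopes, validation table and the report file list.
#' @export
run_pipeline <- function(config) {
  subj <- stage_phantom(config)
  scr <- stage_screen(config)
  rng <- stage_doe1(config)
  opt <- stage_optimize(config)
  fits <- stage_fitdist(config)
  envs <- stage_doe2(config)
  val <- stage_validate(config)
  rep <- stage_report(config)
  invisible(list(subjects = subj, screening = scr, doe1_ranges = rng,
                 candidates = opt, weibull_fits = fits, envelopes = envs,
                 validation = val, report = rep))
}
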