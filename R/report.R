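# Reporting stage: figures (range bars, material histograms with fitted
# curves, landmark probability histograms with cumulative densities, midline
# profile bands) and a machine-readable JSON summary of a completed run.

.report_required <- c(subjects = "subjects.csv", screen = "screening.json",
                      doe1 = "doe1_ranges.json", fitdist = "weibull_fits.json",
                      doe2 = "envelopes.json", validate = "validation.csv")

#' Report stage: figures and JSON summary
#'
#' Requires a completed run directory; errors listing the missing stages
#' otherwise. Writes, under `figures/`: the DOE I vs DOE II range bars with
#' the observed displacements, the pooled material histograms with the fitted
#' Weibull density and cumulative curves, per-validation-subject landmark
#' probability histograms with cumulative densities, and the midline profile
#' bands; plus `summary.json` in the run directory. The summary contains only
#' quantities computed by the run, no timestamps, so a rerun with identical
#' seeds reproduces it byte for byte.
#'
#' @param config a [pipeline_config()] (its `outdir` names the run).
#' @return character vector of written file paths, invisibly.
#' @export
stage_report <- function(config) {
  outdir <- config$outdir
  present <- file.exists(file.path(outdir, .report_required))
  if (!all(present))
    stopf("incomplete run directory %s: missing stage output for %s", outdir,
          paste(names(.report_required)[!present], collapse = ", "))
  envs <- jsonlite::read_json(file.path(outdir, "envelopes.json"),
                              simplifyVector = TRUE)
  if (length(envs) == 0L) stopf("empty envelope set: DOE II produced no envelopes")
  subj <- utils::read.csv(file.path(outdir, "subjects.csv"))
  rngs <- jsonlite::read_json(file.path(outdir, "doe1_ranges.json"),
                              simplifyVector = TRUE)
  scr <- jsonlite::read_json(file.path(outdir, "screening.json"),
                             simplifyVector = TRUE)
  fits <- jsonlite::read_json(file.path(outdir, "weibull_fits.json"),
                              simplifyVector = TRUE)
  val <- utils::read.csv(file.path(outdir, "validation.csv"))
  figdir <- file.path(outdir, "figures")
  dir.create(figdir, showWarnings = FALSE)
  files <- character(0)

  files <- c(files, .fig_ranges(figdir, subj, rngs, envs))
  pooled_f <- file.path(outdir, "pooled_candidates.csv")
  if (file.exists(pooled_f))
    files <- c(files, .fig_materials(figdir, utils::read.csv(pooled_f), fits))
  for (id in names(envs)) {
    files <- c(files, .fig_landmark_hist(figdir, id, envs[[id]]))
    mid_f <- file.path(outdir, sprintf("midline_%s.csv", id))
    if (file.exists(mid_f))
      files <- c(files, .fig_midline(figdir, id, utils::read.csv(mid_f)))
  }

  summary <- list(
    preset = config$preset, seed = config$seed,
    screening = scr,
    doe1_ranges = rngs,
    weibull_fits = fits,
    envelopes = lapply(envs, function(e)
      lapply(e, function(l) l[c("min", "max", "truth", "contains_truth")])),
    validation = val)
  sf <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_stage(config, "report", list(figures = length(files)))
  invisible(c(files, sf))
}

.ggsave_quiet <- function(path, plot, width = 8, height = 5) {
  suppressMessages(ggplot2::ggsave(path, plot, width = width, height = height,
                                   dpi = 120))
  path
}

# DOE I (all subjects) vs DOE II (validation) ranges with observed truths
.fig_ranges <- function(figdir, subj, rngs, envs) {
  lms <- c("N", "UL", "LL", "RC", "LC")
  rows <- list()
  for (id in names(rngs)) {
    for (nm in lms) {
      r <- as.numeric(rngs[[id]][[nm]])
      rows[[length(rows) + 1L]] <- data.frame(patient = id, landmark = nm,
                                              lo = r[1], hi = r[2], stage = "DOE I")
    }
  }
  for (id in names(envs)) {
    for (nm in lms) {
      e <- envs[[id]][[nm]]
      rows[[length(rows) + 1L]] <- data.frame(patient = id, landmark = nm,
                                              lo = e$min, hi = e$max, stage = "DOE II")
    }
  }
  df <- do.call(rbind, rows)
  df$landmark <- factor(df$landmark, levels = lms)
  tr <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i)
    data.frame(patient = subj$patient[i], landmark = factor(lms, levels = lms),
               truth = as.numeric(subj[i, paste0("obs_", lms)]))))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$patient)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                         colour = .data$stage),
                            position = ggplot2::position_dodge(width = 0.5),
                            linewidth = 2, alpha = 0.8) +
    ggplot2::geom_point(data = tr, ggplot2::aes(y = .data$truth), shape = 16,
                        size = 1.5) +
    ggplot2::scale_colour_manual(values = c("DOE I" = "#c0392b", "DOE II" = "#2980b9")) +
    ggplot2::facet_wrap(~landmark, scales = "free_y") +
    ggplot2::labs(y = "anterior displacement (mm)", x = NULL,
                  title = "Prediction ranges vs observed displacement") +
    ggplot2::theme_bw()
  .ggsave_quiet(file.path(figdir, "fig_ranges.png"), p, width = 9, height = 6)
}

.fig_materials <- function(figdir, pooled, fits) {
  dfs <- list()
  curves <- list()
  for (nm in names(fits)) {
    if (!nm %in% names(pooled)) next
    x <- pooled[[nm]]
    dfs[[nm]] <- data.frame(parameter = nm, value = x)
    f <- fits[[nm]]
    xs <- seq(min(x), max(x), length.out = 200)
    dens <- stats::dweibull(xs - f$location, f$shape, f$scale)
    cdf <- stats::pweibull(xs - f$location, f$shape, f$scale)
    curves[[nm]] <- data.frame(parameter = nm, x = xs, density = dens,
                               cdf_scaled = cdf * max(dens))
  }
  dd <- do.call(rbind, dfs)
  cc <- do.call(rbind, curves)
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 20, fill = "#27ae60", colour = "grey30",
                            alpha = 0.7) +
    ggplot2::geom_line(data = cc, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line(data = cc, ggplot2::aes(x = .data$x, y = .data$cdf_scaled),
                       linetype = "dotted") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "density",
                  title = "Optimised material properties with fitted Weibull curves") +
    ggplot2::theme_bw()
  .ggsave_quiet(file.path(figdir, "fig_materials.png"), p, width = 8, height = 6)
}

.fig_landmark_hist <- function(figdir, id, env) {
  rows <- list()
  cdfs <- list()
  truths <- list()
  for (nm in names(env)) {
    e <- env[[nm]]
    br <- as.numeric(e$breaks)
    ct <- as.numeric(e$counts)
    rows[[nm]] <- data.frame(landmark = nm, xmin = br[-length(br)], xmax = br[-1],
                             count = ct)
    cdfs[[nm]] <- data.frame(landmark = nm, x = as.numeric(e$cdf_x),
                             p = as.numeric(e$cdf_p) * max(ct))
    truths[[nm]] <- data.frame(landmark = nm, truth = e$truth)
  }
  df <- do.call(rbind, rows)
  cdf <- do.call(rbind, cdfs)
  tr <- do.call(rbind, truths)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = 0, ymax = .data$count),
                       fill = "#2980b9", colour = "grey30", alpha = 0.8) +
    ggplot2::geom_step(data = cdf, ggplot2::aes(x = .data$x, y = .data$p),
                       linetype = "dotted") +
    ggplot2::geom_vline(data = tr, ggplot2::aes(xintercept = .data$truth),
                        colour = "black", linewidth = 0.7) +
    ggplot2::facet_wrap(~landmark, scales = "free") +
    ggplot2::labs(x = "anterior displacement (mm)", y = "runs",
                  title = sprintf("%s: prediction probability histograms", id)) +
    ggplot2::theme_bw()
  .ggsave_quiet(file.path(figdir, sprintf("fig_landmarks_%s.png", id)), p,
                width = 8, height = 6)
}

.fig_midline <- function(figdir, id, mid) {
  p <- ggplot2::ggplot(mid, ggplot2::aes(y = .data$z)) +
    ggplot2::geom_ribbon(ggplot2::aes(xmin = .data$y_lo, xmax = .data$y_hi),
                         fill = "#2980b9", alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.6) +
    ggplot2::labs(x = "anterior displacement (mm)", y = "height z (mm)",
                  title = sprintf("%s: midline prediction band (0 = preoperative)", id)) +
    ggplot2::theme_bw()
  .ggsave_quiet(file.path(figdir, sprintf("fig_midline_%s.png", id)), p,
                width = 5, height = 6)
}
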