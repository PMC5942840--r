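# Per-landmark prediction envelopes: min/max range, histogram, cumulative
# density and truth containment over the runs of a probabilistic DOE.

#' Build per-landmark prediction envelopes
#'
#' @param responses n-by-5 matrix of landmark displacements (columns N, UL,
#'   LL, RC, LC), one row per DOE run.
#' @param truths optional named numeric of observed displacements (mm).
#' @return object of class `prediction_envelope_set`: per landmark `min`,
#'   `max`, `breaks`, `counts` (Freedman-Diaconis histogram), `cdf_x`/`cdf_p`
#'   (empirical cumulative density), `truth`, `contains_truth`.
#' @export
build_envelope <- function(responses, truths = NULL) {
  Y <- as.matrix(responses)
  if (nrow(Y) < 1L) stopf("empty response set")
  envs <- lapply(colnames(Y), function(nm) {
    x <- Y[, nm]
    if (diff(range(x)) == 0) {
      h <- diff(range(Y))
      h <- if (h > 0) h * 0.01 else 0.01
      breaks <- c(x[1] - h / 2, x[1] + h / 2)
      counts <- length(x)
    } else {
      hh <- grDevices::nclass.FD(x)
      hist_ <- graphics::hist(x, breaks = max(hh, 1L), plot = FALSE)
      breaks <- hist_$breaks
      counts <- hist_$counts
    }
    truth <- if (!is.null(truths) && nm %in% names(truths)) unname(truths[nm]) else NA_real_
    list(min = min(x), max = max(x), breaks = breaks, counts = counts,
         cdf_x = sort(x), cdf_p = seq_along(x) / length(x),
         truth = truth,
         contains_truth = if (is.na(truth)) NA else truth >= min(x) & truth <= max(x))
  })
  names(envs) <- colnames(Y)
  structure(list(landmarks = envs, n_runs = nrow(Y)),
            class = "prediction_envelope_set")
}

#' @export
print.prediction_envelope_set <- function(x, ...) {
  df <- do.call(rbind, lapply(names(x$landmarks), function(nm) {
    e <- x$landmarks[[nm]]
    data.frame(landmark = nm, min = e$min, max = e$max, truth = e$truth,
               contains = e$contains_truth)
  }))
  cat(sprintf("prediction envelopes over %d runs:\n", x$n_runs))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Validate prediction envelopes against observed displacements
#'
#' Reports, per landmark, whether the truth lies inside the envelope, the
#' distance to the envelope when outside, and (when first-iteration ranges are
#' given) whether the refined range is no wider than the first-iteration
#' range. A landmark without an available truth is reported as not validated
#' rather than raising an error.
#'
#' @param envelopes a `prediction_envelope_set`.
#' @param truths named numeric of observed displacements (may be missing
#'   entries).
#' @param doe1_ranges optional named list of `c(min, max)` per landmark from
#'   the first DOE iteration.
#' @return data.frame with one row per landmark: `landmark`, `validated`,
#'   `contains_truth`, `distance`, `width`, `doe1_width`, `refined`.
#' @export
validate_envelopes <- function(envelopes, truths, doe1_ranges = NULL) {
  rows <- lapply(names(envelopes$landmarks), function(nm) {
    e <- envelopes$landmarks[[nm]]
    truth <- if (nm %in% names(truths)) unname(truths[nm]) else NA_real_
    validated <- !is.na(truth)
    dist <- if (!validated) NA_real_ else max(0, e$min - truth, truth - e$max)
    w1 <- if (!is.null(doe1_ranges) && nm %in% names(doe1_ranges))
      diff(doe1_ranges[[nm]]) else NA_real_
    data.frame(landmark = nm, validated = validated,
               contains_truth = if (validated) dist == 0 else NA,
               distance = dist, width = e$max - e$min, doe1_width = w1,
               refined = if (is.na(w1)) NA else (e$max - e$min) <= w1)
  })
  do.call(rbind, rows)
}
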