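#' Field-tracking summary of a circuit-model experiment
#'
#' Runs Stage 1-4 tracking, rotation-bootstrap shift classification and
#' reset-event detection on a subset of the recorded model cells, using
#' thresholds suited to the model's drift scale.
#'
#' @param sim Result of \code{\link{run_experiment}}.
#' @param params \code{link_params} (default the \code{"model"} preset).
#' @param cells Indices of recorded cells to analyze.
#' @param n_shuffles Stage-1 rotations per run.
#' @param seed Integer seed.
#' @param min_runs_per_day Strict run minimum for reset-event day fields.
#' @param reset_pct Percentile for reset significance (70 for the simulated
#'   environment).
#' @return List: \code{cells} (per-cell lists of \code{cross_day_field}),
#'   \code{labels}, \code{slopes}, \code{n_regression},
#'   \code{n_progression} (significant events only).
#' @export
circuit_field_summary <- function(sim, params = link_params("model"),
                                  cells = seq(1, 120, by = 4),
                                  n_shuffles = 150, seed = 1,
                                  min_runs_per_day = 3, reset_pct = 70) {
  dr <- day_run_ranges(sim$maps[[1]])
  labels <- character(0); slopes <- numeric(0)
  nregr <- 0L; nprog <- 0L
  per_cell <- list()
  for (ci in cells) {
    map <- sim$maps[[ci]]
    fl <- track_fields(map, params, n_shuffles = n_shuffles,
                       seed = rng_seed(seed, sprintf("track/%d", ci)))
    per_cell[[length(per_cell) + 1L]] <- fl
    for (f in fl) {
      cl <- classify_shift(f)
      labels <- c(labels, cl$label)
      slopes <- c(slopes, cl$slope_cm_per_run)
      ev <- detect_reset_events(f, dr, min_runs_per_day = min_runs_per_day)
      if (nrow(ev)) for (i in seq_len(nrow(ev))) {
        if (reset_significance(ev[i, ], f, pct = reset_pct)$significant) {
          if (ev$kind[i] == "regression") nregr <- nregr + 1L
          else nprog <- nprog + 1L
        }
      }
    }
  }
  list(cells = per_cell, labels = labels, slopes = slopes,
       n_regression = nregr, n_progression = nprog)
}

#' Landmark influence index of a circuit-model experiment
#'
#' Extracts per-cell spectral phases from the day-averaged 1-cm activity of
#' the requested days, builds per-run population phase trajectories, and
#' returns the per-run landmark influence indices (5-cm landmark expansion,
#' the simulated-environment convention).
#'
#' @param sim Result of \code{\link{run_experiment}}.
#' @param days Days whose runs enter the analysis.
#' @param expand_cm Landmark expansion half-width (default 5).
#' @return Numeric vector of per-run influence indices.
#' @export
circuit_influence_index <- function(sim, days, expand_cm = 5) {
  idx <- which(sim$day_of_run %in% days)
  stopifnot(length(idx) > 0)
  avg <- Reduce(`+`, lapply(sim$runs[idx], function(r) r$vectors)) /
    length(idx)
  n_cells <- ncol(avg)
  phases <- matrix(NA_real_, n_cells, 3)
  ok <- logical(n_cells)
  for (ci in seq_len(n_cells)) {
    sp <- cell_spectrum(avg[, ci])
    if (sp$qualified) { phases[ci, ] <- sp$phi; ok[ci] <- TRUE }
  }
  stopifnot(sum(ok) >= 3)
  lay <- track_layout(1000, sim$maps[[1]]$layout$landmark_edges_cm,
                      reward_span_cm = sim$maps[[1]]$layout$reward_span_cm,
                      bin_size_cm = 1,
                      landmark_sides = sim$maps[[1]]$layout$landmark_sides)
  trajs <- lapply(idx, function(r) {
    rates <- t(sim$runs[[r]]$vectors[, ok, drop = FALSE])
    population_phase(phases[ok, 1:2, drop = FALSE], rates,
                     x = sim$runs[[r]]$positions, source = "run")
  })
  pj <- phase_jumps(trajs, lay, expand_cm = expand_cm)
  pj$per_run$influence_index
}
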