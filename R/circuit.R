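#' Configuration of the entorhinal-hippocampal circuit model
#'
#' Builds the parameter list for \code{\link{run_experiment}}. The
#' \code{"full"} preset follows the published architecture (128 x 128 grid
#' sheet, 2000 hippocampal and 200 sensory cells, 5000 timesteps per run);
#' the \code{"scaled"} preset (48 x 48 sheet, 500/100 cells, 1500 steps per
#' run, 4 runs/day over 8 days) keeps the same dynamical regime at desk
#' scale and is used throughout the test suite.
#'
#' @param preset \code{"scaled"} (default) or \code{"full"}.
#' @param layout A \code{track_layout}; defaults to the 1000-cm track with
#'   8 landmarks and the reward span between the last two.
#' @param tau Hippocampus-to-grid plasticity delay in timesteps (default
#'   16; 0 disables the delay).
#' @param tau_c Consolidation lag in runs (default 4; 0 disables overnight
#'   resets).
#' @param plastic Enable plasticity in the novel environment (pretraining
#'   always learns).
#' @param ... Named overrides of any config entry.
#' @return A named list understood by \code{\link{run_experiment}}.
#' @export
sim_config <- function(preset = c("scaled", "full"), layout = NULL,
                       tau = 16, tau_c = NULL, plastic = TRUE, ...) {
  preset <- match.arg(preset)
  # consolidation lag scales with the session length: 4 runs against the
  # full 16-run days, 2 against the scaled 4-run days
  if (is.null(tau_c)) tau_c <- if (preset == "scaled") 2L else 4L
  if (is.null(layout)) layout <- default_track_layout()
  side_code <- c(left = 0L, right = 1L, both = 2L)
  base <- list(
    n = if (preset == "scaled") 48L else 128L,
    n_h = if (preset == "scaled") 500L else 2000L,
    n_s = if (preset == "scaled") 100L else 200L,
    steps_per_run = if (preset == "scaled") 1500L else 5000L,
    runs_per_day = if (preset == "scaled") rep(4L, 8) else rep(16L, 10),
    pretrain_runs = 20L,
    track_length = layout$length_cm,
    landmark_pos = layout$landmark_edges_cm,
    landmark_side = unname(side_code[layout$landmark_sides]),
    landmark_width = layout$landmark_width_cm,
    update_period = 20L,
    relax_steps = 15L,
    tau = as.integer(tau),
    tau_c = as.integer(tau_c),
    gamma_s = 0.1,
    gamma_h = 1,
    v_gain = 0.6,             # sheet velocity input per cm/step of track;
                              # calibrated for a ~215-cm track period
    vel_noise_sd = 0.01,
    sens_noise_sd = 0.05,
    sens_burst = 1L,
    sens_gain = 1 - (1 - 0.1)^15,
    whs_eta = 0.1,
    rls_delta = 0.1,
    sparsity = 0.15,
    plastic = isTRUE(plastic),
    record_bins = 1000L,
    lambda = 13,
    alpha = 0.10315,
    ell = 2L,
    dt = 0.2,
    w_amp = 3,
    init_aper = 250L,
    init_per = 750L)
  over <- list(...)
  base[names(over)] <- over
  base$layout <- layout
  base
}

#' Default experimental track layout
#'
#' 1000-cm track, 8 landmark front edges with the reward span between the
#' last two landmarks (863-909 cm), 2.5-cm analysis bins.
#' @param bin_size_cm Bin size (default 2.5).
#' @return A \code{track_layout}.
#' @export
default_track_layout <- function(bin_size_cm = 2.5) {
  track_layout(1000, c(120, 240, 360, 480, 600, 740, 863, 909),
               reward_span_cm = c(863, 909), bin_size_cm = bin_size_cm,
               landmark_sides = rep(c("left", "right"), 4))
}

# Evenly spaced cells on the sheet (regular subgrid), so recorded cells
# sample the grid phases evenly.
even_record_cells <- function(n, n_cells = 120) {
  k1 <- ceiling(sqrt(n_cells))
  k2 <- ceiling(n_cells / k1)
  rows <- round(seq(1, n, length.out = k1 + 1)[-(k1 + 1)])
  cols <- round(seq(1, n, length.out = k2 + 1)[-(k2 + 1)])
  idx <- as.vector(outer(rows, (cols - 1) * n, "+"))
  sort(idx)[seq_len(n_cells)]
}

#' Simulate the circuit model over a learning schedule
#'
#' Runs the continuous-attractor grid sheet with hippocampal feedback:
#' noisy path integration, hippocampus-to-grid recall every 20th timestep
#' (followed by attractor relaxation), delayed online-pseudoinverse weight
#' updates, sensory anchoring at every landmark, and an overnight reset of
#' the fast weights to the consolidated copy lagging \code{tau_c} runs.
#' After 20 pretraining runs in a random-cue environment, the novel
#' environment is simulated over the configured day schedule and the
#' activity of 120 evenly phase-sampled grid cells is recorded in 1-cm
#' position bins.
#'
#' @param config From \code{\link{sim_config}}.
#' @param seed Integer seed.
#' @return List: \code{runs} (per-run list with \code{vectors} positions x
#'   cells and \code{positions}), \code{maps} (per-cell
#'   \code{run_activity_map} at the layout's bin size), \code{weight_norm}
#'   (Frobenius norm of the fast hippocampus-to-grid weights per run),
#'   \code{day_of_run}, \code{theta}, \code{sheet} (final sheet state).
#' @export
run_experiment <- function(config, seed = 1) {
  layout <- config$layout
  cfg <- config[setdiff(names(config), "layout")]
  cfg$record_cells <- as.integer(even_record_cells(config$n, 120))
  res <- run_circuit_cpp(cfg, as.integer(seed))
  nb <- cfg$record_bins
  pos <- (seq_len(nb) - 0.5) * cfg$track_length / nb
  runs <- lapply(res$activity, function(m)
    list(vectors = t(m), positions = pos))
  # rebin 1-cm records to the layout's analysis bins
  bin_idx <- pmin(floor(pos / layout$bin_size_cm) + 1L, layout$n_bins)
  n_cells <- nrow(res$activity[[1]])
  n_runs <- length(res$activity)
  maps <- lapply(seq_len(n_cells), function(ci) {
    vals <- t(vapply(res$activity, function(m)
      as.numeric(tapply(m[ci, ], bin_idx, mean)), numeric(layout$n_bins)))
    run_activity_map(vals, res$day_of_run, layout,
                     cell_id = sprintf("model%03d", ci))
  })
  list(runs = runs, maps = maps, weight_norm = res$weight_norm,
       recall_corr = res$recall_corr, day_of_run = res$day_of_run,
       theta = res$theta, sheet = res$sheet)
}

#' Six-fold symmetry score of a grid sheet
#'
#' Measures hexagonality from the 2D Fourier power of the (mean-removed)
#' sheet: power is pooled into annular rings, the dominant non-DC ring is
#' selected, and the score is the magnitude of the 6th angular Fourier
#' coefficient of the power distribution on that ring relative to the total
#' ring power. A triangular lattice scores near 1; unstructured activity
#' scores near 0.
#'
#' @param sheet n x n activity matrix.
#' @return Score in [0, 1].
#' @export
hexagonality_score <- function(sheet) {
  n <- nrow(sheet)
  P <- Mod(stats::fft(sheet - mean(sheet)))^2
  fx <- ifelse(0:(n - 1) > n / 2, 0:(n - 1) - n, 0:(n - 1))
  FX <- matrix(fx, n, n)
  FY <- matrix(fx, n, n, byrow = TRUE)
  R <- sqrt(FX^2 + FY^2)
  ring_r <- round(R)
  pw <- tapply(P, ring_r, sum)
  radii <- as.numeric(names(pw))
  keep <- radii >= 2
  r0 <- radii[keep][which.max(pw[keep])]
  sel <- ring_r == r0
  th <- atan2(FY[sel], FX[sel])
  p <- P[sel]
  # 6-fold minus 4-fold angular concentration: triangular lattices score
  # near 1, stripes near 0, square lattices negative
  (Mod(sum(p * exp(6i * th))) - Mod(sum(p * exp(4i * th)))) / sum(p)
}

#' Optimal translation between two periodic sheet patterns
#'
#' Finds the 2D circular shift maximizing the cross-correlation of two
#' sheet states (via FFT) and the pattern correlation at that shift; used
#' to verify that the attractor state moves as a rigid translation under
#' path integration.
#'
#' @param a,b n x n matrices.
#' @return List: \code{shift} (dx, dy in neurons, in (-n/2, n/2]),
#'   \code{correlation}.
#' @export
sheet_shift <- function(a, b) {
  n <- nrow(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- Re(stats::fft(Conj(stats::fft(a0)) * stats::fft(b0), inverse = TRUE))
  ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  shift <- ((ij - 1 + n / 2) %% n) - n / 2
  # b translated back by the detected shift, circularly
  bs <- b0[((seq_len(n) - 1 + ij[1] - 1) %% n) + 1,
           ((seq_len(n) - 1 + ij[2] - 1) %% n) + 1]
  list(shift = unname(shift),
       correlation = stats::cor(as.vector(a0), as.vector(bs)))
}
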