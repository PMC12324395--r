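#' Planted field specification for the synthetic-cell generator
#'
#' Describes one spatial field with a known center-of-mass trajectory:
#' linear run-by-run drift (negative slope = backward shift), optional
#' arrest near a landmark anchor, per-run COM jitter, a per-run field-miss
#' probability, and a forward reset ("regression") applied at each day
#' boundary.
#'
#' @param com0_cm Initial COM in cm.
#' @param slope_cm_per_run Drift per run in cm (negative = backward).
#' @param anchor_cm Optional anchor position (a landmark front edge) at
#'   which the drift arrests; drift decays linearly to zero within
#'   \code{arrest_halfwidth_cm} of the anchor.
#' @param arrest_halfwidth_cm Arrest zone half-width in cm.
#' @param width_cm Field width (must be at least 3 bins so Stage-1 detection
#'   can find it); the generated bump is Gaussian with sd = width/4.
#' @param amplitude Peak activity value.
#' @param com_jitter_sd_cm Per-run Gaussian COM jitter sd in cm.
#' @param miss_prob Per-run probability in [0, 1) that the field is absent.
#' @param day_regression_cm Forward COM reset applied at each day boundary.
#' @param day_regression_prob Probability the reset is applied at a given
#'   boundary (1 = deterministic).
#' @return A \code{planted_field} list.
#' @export
planted_field <- function(com0_cm, slope_cm_per_run = 0, anchor_cm = NULL,
                          arrest_halfwidth_cm = 50, width_cm = 20,
                          amplitude = 1, com_jitter_sd_cm = 0,
                          miss_prob = 0, day_regression_cm = 0,
                          day_regression_prob = 1) {
  stopifnot(miss_prob >= 0, miss_prob < 1, width_cm > 0, amplitude > 0)
  structure(list(com0_cm = com0_cm, slope_cm_per_run = slope_cm_per_run,
                 anchor_cm = anchor_cm,
                 arrest_halfwidth_cm = arrest_halfwidth_cm,
                 width_cm = width_cm, amplitude = amplitude,
                 com_jitter_sd_cm = com_jitter_sd_cm, miss_prob = miss_prob,
                 day_regression_cm = day_regression_cm,
                 day_regression_prob = day_regression_prob),
            class = "planted_field")
}

#' Default run schedule
#'
#' @param days Number of learning days.
#' @param runs_per_day Runs per day (recycled to \code{days}).
#' @return Integer vector of runs per day.
#' @export
run_plan <- function(days = 10, runs_per_day = 16) {
  rep_len(as.integer(runs_per_day), days)
}

# True (noiseless, jitter-free) COM trajectory of one planted field over a
# run schedule, applying drift, arrest and day-boundary regression.
true_com_trajectory <- function(field, plan, layout, reset_draws = NULL) {
  n_runs <- sum(plan)
  day_of_run <- rep(seq_along(plan), times = plan)
  com <- numeric(n_runs)
  cur <- field$com0_cm
  clipped <- FALSE
  for (r in seq_len(n_runs)) {
    if (r > 1 && day_of_run[r] != day_of_run[r - 1]) {
      apply_reset <- if (is.null(reset_draws)) TRUE else reset_draws[day_of_run[r] - 1]
      if (apply_reset) cur <- cur + field$day_regression_cm
    }
    if (r > 1 || FALSE) NULL
    com[r] <- cur
    eff <- field$slope_cm_per_run
    if (!is.null(field$anchor_cm) && field$arrest_halfwidth_cm > 0) {
      d <- if (field$slope_cm_per_run < 0) cur - field$anchor_cm else field$anchor_cm - cur
      eff <- eff * min(1, max(0, d / field$arrest_halfwidth_cm))
    }
    cur <- cur + eff
    if (cur < 0) { cur <- 0; clipped <- TRUE }
    if (cur > layout$length_cm) { cur <- layout$length_cm; clipped <- TRUE }
  }
  list(com = com, day_of_run = day_of_run, clipped = clipped)
}

#' Generate one synthetic cell with planted drifting fields
#'
#' Each present field is rendered as a Gaussian bump (sd = width/4) at its
#' drifted, jittered COM; additive truncated-at-zero Gaussian noise is added
#' per bin. The returned ground truth records the noiseless COM of every
#' field at every run, presence indicators, and clipping warnings.
#'
#' @param fields A \code{planted_field} or list of them.
#' @param plan Integer vector of runs per day (see \code{\link{run_plan}}).
#' @param layout A \code{track_layout}.
#' @param noise_sd Noise sd (each bin gets \code{max(N(0, noise_sd), 0)}).
#' @param seed Integer seed.
#' @param cell_id Cell identifier.
#' @return List with elements \code{map} (a \code{run_activity_map}) and
#'   \code{truth} (list: \code{com} fields x runs matrix of true COMs,
#'   \code{present} logical matrix, \code{clipped} flag vector).
#' @examples
#' lay <- track_layout(1000, c(300, 700))
#' pf <- planted_field(500, slope_cm_per_run = -0.2)
#' g <- generate_cell(pf, run_plan(8, 10), lay, noise_sd = 0, seed = 1)
#' @export
generate_cell <- function(fields, plan, layout, noise_sd = 0.05, seed = 1,
                          cell_id = "synth") {
  if (inherits(fields, "planted_field")) fields <- list(fields)
  stopifnot(all(vapply(fields, inherits, TRUE, "planted_field")))
  for (f in fields) {
    if (f$width_cm < 3 * layout$bin_size_cm)
      stop("field width must be at least 3 bins for Stage-1 detectability")
    if (f$com0_cm < 0 || f$com0_cm > layout$length_cm)
      stop("field does not fit on the track")
  }
  n_runs <- sum(plan)
  centers <- bin_centers(layout)
  with_seed(seed, {
    nf <- length(fields)
    com_true <- matrix(NA_real_, nf, n_runs)
    present <- matrix(TRUE, nf, n_runs)
    clipped <- logical(nf)
    vals <- matrix(0, n_runs, layout$n_bins)
    day_of_run <- rep(seq_along(plan), times = plan)
    for (k in seq_len(nf)) {
      f <- fields[[k]]
      resets <- if (f$day_regression_prob < 1)
        stats::runif(length(plan) - 1) < f$day_regression_prob else NULL
      tr <- true_com_trajectory(f, plan, layout, resets)
      com_true[k, ] <- tr$com
      clipped[k] <- tr$clipped
      present[k, ] <- stats::runif(n_runs) >= f$miss_prob
      jit <- stats::rnorm(n_runs, 0, f$com_jitter_sd_cm)
      sd_bump <- f$width_cm / 4
      for (r in seq_len(n_runs)) {
        if (!present[k, r]) next
        mu <- min(max(tr$com[r] + jit[r], 0), layout$length_cm)
        vals[r, ] <- vals[r, ] +
          f$amplitude * exp(-(centers - mu)^2 / (2 * sd_bump^2))
      }
    }
    if (noise_sd > 0)
      vals <- vals + pmax(matrix(stats::rnorm(length(vals), 0, noise_sd),
                                 nrow(vals)), 0)
    if (any(clipped)) warning("field trajectory clipped at track bounds")
    map <- run_activity_map(vals, day_of_run, layout, cell_id = cell_id)
    list(map = map,
         truth = list(com = com_true, present = present, clipped = clipped,
                      day_of_run = day_of_run))
  })
}

#' Co-modular population specification
#'
#' A module of grid cells generated as 1D slices through one shared 2D
#' triangular lattice, so all phase relationships are known. The lattice has
#' wavevectors at 0, 120 and 60 degrees with the third equal to the sum of
#' the first two, hence the three spatial frequencies along any valid slice
#' satisfy f3 = f1 + f2 exactly by construction.
#'
#' @param n_cells Number of cells (>= 1).
#' @param spacing_cm Lattice period in cm.
#' @param slice_angle Angle (radians) of the 1D track cut through the 2D
#'   lattice; angles for which any component frequency falls to zero (slice
#'   aligned with a lattice axis) are rejected as degenerate.
#' @param phase_offsets Optional n x 2 matrix of per-cell phase offsets
#'   (radians) for the two primary lattice components; defaults to offsets
#'   drawn uniformly on the torus (fixed across runs and days).
#' @param planted_jumps List of \code{c(x_cm, d1, d2)} population phase
#'   jumps (radians) applied to all cells for positions >= x_cm.
#' @param drift_per_day Length-2 phase drift (radians/day) applied to the
#'   whole population trajectory.
#' @param amplitude Peak rate; \code{sharpness} exponentiates the lattice to
#'   sharpen bumps (monotone transform, leaves frequencies in place).
#' @return A \code{module_spec} list (includes the component frequencies
#'   \code{f_cm} in cycles/cm).
#' @export
module_spec <- function(n_cells = 12, spacing_cm = 33, slice_angle = 1.313,
                        phase_offsets = NULL, planted_jumps = list(),
                        drift_per_day = c(0, 0), amplitude = 1,
                        sharpness = 1.5) {
  stopifnot(n_cells >= 1, spacing_cm > 0)
  kmag <- 4 * pi / (sqrt(3) * spacing_cm)
  ang <- c(0, 2 * pi / 3)                      # primary wavevector angles
  u <- c(cos(slice_angle), sin(slice_angle))
  k1 <- kmag * c(cos(ang[1]), sin(ang[1]))
  k2 <- kmag * c(cos(ang[2]), sin(ang[2]))
  w <- c(sum(k1 * u), sum(k2 * u))             # rad per cm along the slice
  w <- c(w, sum(w))
  if (any(abs(w) < 1e-9))
    stop("degenerate slice: slice_angle aligned with a lattice axis")
  if (any(w < 0))
    stop("slice_angle must give positive frequencies for all components; use an angle in (pi/6, pi/2)")
  structure(list(n_cells = as.integer(n_cells), spacing_cm = spacing_cm,
                 slice_angle = slice_angle, phase_offsets = phase_offsets,
                 planted_jumps = planted_jumps,
                 drift_per_day = drift_per_day, amplitude = amplitude,
                 sharpness = sharpness, omega = w, f_cm = w / (2 * pi)),
            class = "module_spec")
}

# Population phase offset (radians, components 1 and 2) at positions x for
# a given day: per-day drift plus planted jumps.
module_delta <- function(mspec, x, day) {
  d1 <- rep((day - 1) * mspec$drift_per_day[1], length(x))
  d2 <- rep((day - 1) * mspec$drift_per_day[2], length(x))
  for (j in mspec$planted_jumps) {
    on <- x >= j[1]
    d1[on] <- d1[on] + j[2]
    d2[on] <- d2[on] + j[3]
  }
  cbind(d1, d2)
}

#' Generate a co-modular population riding one phase torus
#'
#' Each cell's 1D rate is the shared sharpened triangular lattice evaluated
#' along the slice at the cell's fixed phase offset, with the population
#' phase trajectory (per-day drift plus planted jumps) applied to all cells
#' alike; truncated Gaussian noise is added per bin.
#'
#' The ground truth stores, per day, the population phase trajectory in the
#' convention recovered by the analysis pipeline: component k of the
#' trajectory at position x is \code{-(w_k x + delta_k(x))} up to a global
#' constant, where \code{w_k} is the angular spatial frequency.
#'
#' @param mspec A \code{module_spec}.
#' @param plan Runs per day.
#' @param layout A \code{track_layout} (1-cm bins recommended for phase
#'   analyses).
#' @param noise_sd Truncated-Gaussian noise sd.
#' @param seed Integer seed.
#' @return List with \code{maps} (list of \code{run_activity_map}),
#'   \code{truth} (phase offsets per cell, per-day true trajectories,
#'   frequencies).
#' @export
generate_module <- function(mspec, plan, layout, noise_sd = 0, seed = 1) {
  stopifnot(inherits(mspec, "module_spec"))
  x <- bin_centers(layout)
  n_runs <- sum(plan)
  day_of_run <- rep(seq_along(plan), times = plan)
  with_seed(seed, {
    ph <- mspec$phase_offsets
    if (is.null(ph))
      ph <- cbind(stats::runif(mspec$n_cells, 0, 2 * pi),
                  stats::runif(mspec$n_cells, 0, 2 * pi))
    stopifnot(nrow(ph) == mspec$n_cells, ncol(ph) == 2)
    w <- mspec$omega
    days <- seq_along(plan)
    deltas <- lapply(days, function(d) module_delta(mspec, x, d))
    maps <- vector("list", mspec$n_cells)
    for (i in seq_len(mspec$n_cells)) {
      vals <- matrix(0, n_runs, length(x))
      for (r in seq_len(n_runs)) {
        d <- day_of_run[r]
        a1 <- w[1] * x + deltas[[d]][, 1] - ph[i, 1]
        a2 <- w[2] * x + deltas[[d]][, 2] - ph[i, 2]
        a3 <- a1 + a2
        rate <- mspec$amplitude *
          exp(mspec$sharpness * (cos(a1) + cos(a2) + cos(a3) - 3))
        if (noise_sd > 0)
          rate <- rate + pmax(stats::rnorm(length(x), 0, noise_sd), 0)
        vals[r, ] <- rate
      }
      maps[[i]] <- run_activity_map(vals, day_of_run, layout,
                                    cell_id = sprintf("m%02d", i))
    }
    truth_traj <- lapply(days, function(d)
      list(psi1 = -(w[1] * x + deltas[[d]][, 1]),
           psi2 = -(w[2] * x + deltas[[d]][, 2])))
    list(maps = maps,
         truth = list(phase_offsets = ph, f_cm = mspec$f_cm,
                      trajectories = truth_traj, x = x,
                      day_of_run = day_of_run))
  })
}
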