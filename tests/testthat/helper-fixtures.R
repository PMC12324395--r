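# Shared fixtures for the suite: small layouts, planted cells, and a
# memoised cache so expensive simulations are computed once per run.

fixture_layout <- function(bin_size_cm = 2.5, length_cm = 1000,
                           landmarks = c(120, 240, 360, 480, 600, 740, 863, 909)) {
  track_layout(length_cm, landmarks, reward_span_cm = c(863, 909),
               bin_size_cm = bin_size_cm,
               landmark_sides = rep(c("left", "right"), length.out = length(landmarks)))
}

# one backward-drifting cell on a two-landmark track
fixture_drifting_cell <- function(slope = -0.2, days = 8, runs_per_day = 10,
                                  noise_sd = 0, jitter = 0, miss = 0,
                                  seed = 1, com0 = 500) {
  lay <- track_layout(1000, c(300, 700))
  generate_cell(planted_field(com0, slope_cm_per_run = slope,
                              com_jitter_sd_cm = jitter, miss_prob = miss),
                run_plan(days, runs_per_day), lay, noise_sd = noise_sd,
                seed = seed)
}

# memoised store for cross-test reuse (e.g. circuit simulations)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# run-field table with plausible bins for a COM sequence (one field per run)
make_shift_field <- function(com, runs = seq_along(com), day = NULL,
                             runs_per_day = 12) {
  if (is.null(day)) day <- (runs - 1) %/% runs_per_day + 1L
  start <- pmax(1L, round(com / 2.5) - 2L)
  data.frame(run = runs, day = day, start_bin = start,
             end_bin = start + 4L, com_cm = com, width_cm = 12.5,
             mean_value = 1, field_id = seq_along(com))
}

# independent OLS oracle used against the package's slope estimator
ols_slope_oracle <- function(x, y) {
  unname(stats::coef(stats::lm(y ~ x))[2])
}

# brute-force shift-classification oracle: enumerate every circular
# rotation of the descending-sorted COMs explicitly via lm()
classify_shift_oracle <- function(run, com) {
  n <- length(com)
  sorted <- sort(com, decreasing = TRUE)
  slopes <- numeric(n)
  for (k in 0:(n - 1)) {
    rot <- sorted[((seq_len(n) - 1 + k) %% n) + 1]
    slopes[k + 1] <- ols_slope_oracle(run, rot)
  }
  obs <- ols_slope_oracle(run, com)
  lo <- stats::quantile(slopes, 0.10, type = 7, names = FALSE)
  hi <- stats::quantile(slopes, 0.90, type = 7, names = FALSE)
  if (obs <= lo) "backward" else if (obs >= hi) "forward" else "stationary"
}
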