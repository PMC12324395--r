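test_that("welch spectrum localizes a pure cosine and its phase", {
  x <- seq(0, 999)
  f0 <- 0.02
  phi0 <- 1.1
  tr <- 1 + cos(2 * pi * f0 * x + phi0)
  sp <- cell_spectrum(tr)
  expect_true(sp$qualified || is.na(sp$f[1]))
  pw <- pwelch_psd(tr)
  pk <- pw$freq[which.max(pw$psd[pw$freq > 0.006])]
  peak_f <- pw$freq[pw$freq > 0.006][which.max(pw$psd[pw$freq > 0.006])]
  expect_lt(abs(peak_f - f0), 1 / 2992 + 1e-12)
  # analytic phase oracle: the zero-padded DFT at the peak bin carries phi0
  X <- fft(c(tr, rep(0, 2992 - 1000)))
  k <- which.min(abs((0:1496) / 2992 - f0))
  # phase at bin center shifted by the frequency mismatch; compare mod 2pi
  ph <- Arg(X[k])
  expect_lt(abs(Arg(exp(1i * (ph - phi0)))), 0.25)
})

test_that("generator slices reproduce f3 = f1 + f2 within grid tolerance", {
  ms <- module_spec(n_cells = 1, phase_offsets = matrix(0.5, 1, 2))
  lay <- track_layout(1000, 500, bin_size_cm = 1)
  gm <- generate_module(ms, run_plan(1, 2), lay, noise_sd = 0, seed = 1)
  tr <- colMeans(gm$maps[[1]]$values)
  sp <- cell_spectrum(tr)
  expect_true(sp$qualified)
  expect_lt(max(abs(sp$f - ms$f_cm)), 2 / 2992)
  expect_lt(abs(sp$f[3] - (sp$f[1] + sp$f[2])), 2 / 2992)
})

test_that("per-cell FFT phases recover planted offsets up to a global phase", {
  ph <- cbind(c(0.3, 1.5, 2.9, 4.2), c(5.5, 0.8, 2.2, 3.7))
  ms <- module_spec(n_cells = 4, phase_offsets = ph)
  lay <- track_layout(1000, 500, bin_size_cm = 1)
  gm <- generate_module(ms, run_plan(1, 2), lay, noise_sd = 0, seed = 1)
  rec <- t(vapply(gm$maps, function(m)
    cell_spectrum(colMeans(m$values))$phi, numeric(3)))
  for (k in 1:2) {
    # recovered phase = const - planted offset (mod 2pi)
    resid <- Arg(exp(1i * (rec[, k] + ph[, k])))
    expect_lt(max(abs(resid - mean(resid))), 0.15)
  }
})

test_that("module assignment separates well-spaced spacing modes", {
  set.seed(5)
  sp <- c(rnorm(30, 40, 2), rnorm(30, 90, 3))
  names(sp) <- sprintf("c%02d", seq_along(sp))
  mods <- assign_modules(sp)
  expect_equal(length(mods), 2)
  expect_setequal(mods[[1]]$cells, names(sp)[1:30])
  # all-identical spacings collapse to one module
  one <- rep(50, 8); names(one) <- letters[1:8]
  expect_length(assign_modules(one), 1)
  expect_error(assign_modules(numeric(0)), "no finite")
})

test_that("module qualification enforces size and frequency-sum rules", {
  pk <- expand.grid(cell = sprintf("c%d", 1:12), day = 1:2)
  pk$f1 <- 0.010; pk$f2 <- 0.014; pk$f3 <- 0.024
  q <- qualify_module(pk)
  expect_true(q$qualifying)
  # ten cells are not enough (> 10 required)
  q10 <- qualify_module(pk[pk$cell %in% sprintf("c%d", 1:10), ])
  expect_false(q10$qualifying)
  # a 10% frequency mismatch disqualifies
  pk2 <- pk; pk2$f3 <- (pk$f1 + pk$f2) / 0.9
  expect_false(qualify_module(pk2)$qualifying)
})

test_that("shearing maps bin coordinates onto the rhombus", {
  expect_equal(shear_bins(0, 0), cbind(s1 = 0, s2 = 0))
  expect_equal(shear_bins(2, 0), cbind(s1 = 2, s2 = sqrt(3)))
  expect_equal(shear_bins(1, 1), cbind(s1 = 1.5, s2 = sqrt(3) / 2))
})

test_that("population phase is the rate-weighted circular mean", {
  phases <- matrix(c(1.2, 1.2, 0.7, 0.7), 2)
  rates <- matrix(runif(2 * 10, 0.1, 1), 2)
  tr <- population_phase(phases, rates)
  expect_equal(tr$psi1, rep(1.2, 10))
  expect_equal(tr$psi2, rep(0.7, 10))
  # antipodal cancellation is flagged and carries the previous value
  ph2 <- matrix(c(0, pi, 1, 1), 2)
  r2 <- matrix(1, 2, 5)
  tr2 <- population_phase(ph2, r2)
  expect_true(all(tr2$flagged))
  expect_error(population_phase(phases, -rates), "non-negative")
})

test_that("recovered module trajectories match ground truth shape", {
  # a module whose cells tile the phase torus uniformly, so the
  # rate-weighted circular mean tracks the bump with little sampling wobble
  gr <- as.matrix(expand.grid(p1 = 2 * pi * (0:5) / 6,
                              p2 = 2 * pi * (0:5) / 6))
  ms <- module_spec(n_cells = 36, phase_offsets = gr)
  lay <- track_layout(1000, 500, bin_size_cm = 1)
  gm <- generate_module(ms, run_plan(1, 2), lay, noise_sd = 0, seed = 8)
  phs <- t(vapply(gm$maps, function(m)
    cell_spectrum(colMeans(m$values))$phi, numeric(3)))
  rates <- t(vapply(gm$maps, function(m) colMeans(m$values), numeric(1000)))
  tr <- population_phase(phs[, 1:2], rates, x = gm$truth$x)
  truth <- gm$truth$trajectories[[1]]
  for (k in 1:2) {
    resid <- (tr[[sprintf("psi%d", k)]] - truth[[sprintf("psi%d", k)]])
    resid <- resid - mean(resid)
    expect_lt(sqrt(mean(resid^2)), 0.1)
  }
})

test_that("trajectory distance obeys identity, translation and periodicity", {
  x <- 0:99
  mk <- function(p1, p2) structure(list(x = x, psi1 = p1, psi2 = p2,
                                        flagged = rep(FALSE, 100),
                                        source = "day"),
                                   class = "phase_trajectory")
  ta <- mk(0.01 * x, 0.02 * x)
  expect_equal(trajectory_distance(ta, ta), 0)
  # uniform translation delta in the sheared frame
  tb <- mk(0.01 * x + 0.4, 0.02 * x)
  expect_equal(trajectory_distance(tb, ta), 0.4, tolerance = 1e-9)
  # 2-pi start offsets are corrected away
  tc <- mk(0.01 * x + 2 * pi, 0.02 * x)
  expect_equal(trajectory_distance(tc, ta), 0, tolerance = 1e-9)
  short <- structure(list(x = 0:4, psi1 = rep(0, 5), psi2 = rep(0, 5),
                          flagged = rep(FALSE, 5), source = "day"),
                     class = "phase_trajectory")
  expect_error(trajectory_distance(ta, short), "mismatch")
  # pseudometric: symmetric and non-negative on same-binned inputs
  td <- mk(0.01 * x + 0.2, 0.02 * x - 0.1)
  expect_equal(trajectory_distance(ta, td), trajectory_distance(td, ta),
               tolerance = 1e-9)
  expect_gte(trajectory_distance(ta, td), 0)
})

test_that("rotation removes lateral shift; scaling grows with position", {
  x <- 0:99
  mk <- function(p1, p2) structure(list(x = x, psi1 = p1, psi2 = p2,
                                        flagged = rep(FALSE, 100),
                                        source = "day"),
                                   class = "phase_trajectory")
  ta <- mk(0.01 * x, 0.02 * x)
  tb <- mk(0.01 * x + 3, 0.02 * x - 1)   # pure translation
  expect_equal(trajectory_rotation(ta, tb), 0, tolerance = 1e-12)
  ts <- mk(0.012 * x, 0.024 * x)         # scaled about the start
  d_half <- trajectory_rotation(mk(0.01 * x[1:50], 0.02 * x[1:50]),
                                mk(0.012 * x[1:50], 0.024 * x[1:50]))
  expect_gt(trajectory_rotation(ta, ts), d_half)
})

test_that("lateral shifts self-normalize within a module", {
  x <- 0:49
  mk <- function(off) structure(list(x = x, psi1 = 0.01 * x + off,
                                     psi2 = 0.02 * x, flagged = rep(FALSE, 50),
                                     source = "day"),
                                class = "phase_trajectory")
  base <- mk(0)
  pairs <- lapply(c(0.3, 0.3, 0.3, 0.6), function(o) list(mk(o), base))
  ls <- lateral_shift(pairs)
  # one pair double the rest of n pairs: normalized value 2n/(n+1)
  expect_equal(ls$normalized[4], 2 * 4 / (4 + 1), tolerance = 1e-9)
  expect_equal(ls$normalized[1], 4 / 5 * 1, tolerance = 1e-9)
  same <- lateral_shift(lapply(1:3, function(i) list(mk(0.2), base)))
  expect_equal(same$normalized, rep(1, 3))
})

test_that("planted landmark jumps raise the influence index", {
  lay <- track_layout(1000, c(240, 480, 740), bin_size_cm = 1)
  mkrun <- function(jump_at, seed) {
    set.seed(seed)
    p1 <- 0.01 * (0:999) + cumsum(ifelse(0:999 %in% jump_at, 0.5, 0)) +
      rnorm(1000, 0, 0.005)
    structure(list(x = bin_centers(lay), psi1 = p1, psi2 = 0.02 * (0:999),
                   flagged = rep(FALSE, 1000), source = "run"),
              class = "phase_trajectory")
  }
  # jumps at landmark 240 in every run
  runs_lm <- lapply(1:10, function(s) mkrun(240, s))
  pj <- phase_jumps(runs_lm, lay, expand_cm = 5)
  expect_true(mean(pj$per_run$influence_index) > 0)
  # straight lines have zero influence index
  runs0 <- lapply(1:5, function(s) mkrun(integer(0), s))
  pj0 <- phase_jumps(runs0, lay, expand_cm = 5)
  expect_lt(abs(mean(pj0$per_run$influence_index)), 0.01)
  # a jump far from any landmark zone pushes the index negative
  runs_mid <- lapply(1:10, function(s) mkrun(600, s))
  pjm <- phase_jumps(runs_mid, lay, expand_cm = 5)
  expect_lte(mean(pjm$per_run$influence_index), 0)
})

test_that("run correlation is 1 for identical runs and ~0 for noise", {
  lay <- track_layout(200, 100, bin_size_cm = 2.5)
  set.seed(3)
  base <- matrix(runif(8 * 80), 8)
  maps <- lapply(1:8, function(i)
    run_activity_map(rbind(base[i, ], base[i, ], runif(80)), c(1, 1, 1), lay,
                     cell_id = sprintf("c%d", i)))
  rc <- run_correlation(maps, run_pairs = cbind(1, 2), n_shuffle = 20,
                        seed = 1)
  expect_equal(rc$run_corr$corr, 1)
  rc2 <- run_correlation(maps, run_pairs = cbind(1, 3), n_shuffle = 20,
                         seed = 1)
  expect_lt(abs(rc2$run_corr$corr), 3 / sqrt(choose(8, 2)))
})

test_that("field trajectory correlations decay with track distance", {
  set.seed(9)
  drift <- cumsum(rnorm(30))
  mkfield <- function(cell, offset, own = 0) {
    com <- offset + drift * (1 - own) + cumsum(rnorm(30)) * own
    structure(list(cell_id = cell, runs = make_shift_field(com)),
              class = "cross_day_field")
  }
  fields <- list(mkfield("a", 100), mkfield("b", 105), mkfield("c", 300, 1))
  fc <- field_trajectory_correlation(fields)
  near <- fc$pairs$correlation[fc$pairs$distance_cm < 20]
  far <- fc$pairs$correlation[fc$pairs$distance_cm > 100]
  expect_gt(min(near), 0.9)
  expect_lt(mean(far), 0.5)
  # identical trajectories at distance 0 correlate perfectly
  dup <- list(mkfield("a", 100), mkfield("b", 100))
  expect_equal(field_trajectory_correlation(dup)$pairs$correlation, 1)
})
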