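test_that("a quiet planted field renders identically every run", {
  lay <- track_layout(1000, c(300, 700))
  g <- generate_cell(planted_field(500, 0), run_plan(2, 3), lay,
                     noise_sd = 0, seed = 1)
  v <- g$map$values
  for (r in 2:6) expect_equal(v[r, ], v[1, ])
  expect_true(all(g$truth$com == 500))
})

test_that("linear drift accumulates exactly without an anchor", {
  g <- fixture_drifting_cell(slope = -0.2, days = 10, runs_per_day = 10)
  expect_equal(g$truth$com[1, 100], 500 - 0.2 * 99)
})

test_that("drift arrests at the anchor and never crosses it", {
  lay <- track_layout(1000, c(300, 700))
  g <- generate_cell(planted_field(320, -1, anchor_cm = 300,
                                   arrest_halfwidth_cm = 50),
                     run_plan(10, 10), lay, noise_sd = 0, seed = 1)
  com <- g$truth$com[1, ]
  expect_true(all(diff(com) <= 0))
  expect_true(all(com >= 300))
  # approaches the anchor asymptotically
  expect_lt(com[100] - 300, 3)
})

test_that("day-boundary regression resets the trajectory forward", {
  lay <- track_layout(1000, c(300, 700))
  g <- generate_cell(planted_field(500, -1, day_regression_cm = 5),
                     run_plan(3, 4), lay, noise_sd = 0, seed = 1)
  com <- g$truth$com[1, ]
  expect_equal(com[5] - com[4], 5 - 1)  # regression minus one run of drift
})

test_that("miss rate is distribution-stable", {
  lay <- track_layout(1000, c(300, 700))
  g <- generate_cell(planted_field(500, 0, miss_prob = 0.2),
                     run_plan(10, 1000), lay, noise_sd = 0, seed = 5)
  rate <- mean(!g$truth$present)
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
})

test_that("module cells with equal phases are identical and slices satisfy f3 = f1 + f2", {
  ms <- module_spec(n_cells = 2, phase_offsets = matrix(1, 2, 2))
  lay <- track_layout(1000, c(500), bin_size_cm = 1)
  gm <- generate_module(ms, run_plan(1, 2), lay, noise_sd = 0, seed = 1)
  expect_equal(gm$maps[[1]]$values, gm$maps[[2]]$values)
  expect_equal(ms$f_cm[3], ms$f_cm[1] + ms$f_cm[2])
  expect_true(all(ms$f_cm > 0.006))
  # a slice along a lattice axis is degenerate
  expect_error(module_spec(slice_angle = pi / 2 + pi / 6), "degenerate|positive")
})

test_that("planted jumps appear as discontinuities in the true trajectory", {
  ms <- module_spec(n_cells = 3, planted_jumps = list(c(400, 0.5, 0)))
  lay <- track_layout(1000, c(500), bin_size_cm = 1)
  gm <- generate_module(ms, run_plan(1, 1), lay, noise_sd = 0, seed = 2)
  tr <- gm$truth$trajectories[[1]]
  x <- gm$truth$x
  step1 <- diff(tr$psi1)
  base <- -ms$omega[1]                 # smooth slope per 1-cm bin
  jump_at <- which(abs(step1 - base) > 0.25)
  expect_length(jump_at, 1)
  expect_equal(x[jump_at + 1], min(x[x >= 400]))
  expect_equal(abs(step1[jump_at] - base), 0.5, tolerance = 1e-9)
})

test_that("no drift and no jumps give a straight-line phase trajectory", {
  ms <- module_spec(n_cells = 3)
  lay <- track_layout(1000, c(500), bin_size_cm = 1)
  gm <- generate_module(ms, run_plan(2, 1), lay, noise_sd = 0, seed = 3)
  tr <- gm$truth$trajectories[[1]]
  expect_equal(max(abs(diff(diff(tr$psi1)))), 0, tolerance = 1e-12)
  # and the day-2 trajectory is identical without drift
  tr2 <- gm$truth$trajectories[[2]]
  expect_equal(tr$psi1, tr2$psi1)
})

test_that("noiseless generator output feeds back through field tracking", {
  g <- fixture_drifting_cell(slope = -0.2, days = 4, runs_per_day = 10)
  fl <- track_fields(g$map, link_params("simulated"), n_shuffles = 300,
                     seed = 4)
  expect_equal(length(fl), 1L)
  f <- fl[[1]]
  err <- abs(f$runs$com_cm - g$truth$com[1, f$runs$run])
  expect_lt(max(err), 2.5 / 2)  # within half a bin
})
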