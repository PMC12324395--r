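test_that("COM follows the activity-weighted mean formula", {
  expect_equal(compute_com(c(1, 1, 1, 1), c(1.25, 3.75, 6.25, 8.75)), 5.0)
  expect_equal(compute_com(c(0, 2), c(1.25, 3.75)), 3.75)
  expect_equal(compute_com(c(1, 3), c(1.25, 3.75)), 3.125)  # direct formula
  expect_error(compute_com(c(0, 0), c(1, 2)), "undefined")
})

test_that("stage-1 detection finds a tall bump and nothing else", {
  lay <- track_layout(100, 50, bin_size_cm = 2.5)  # 40 bins
  trace <- rep(0.01, 40)
  trace[18:22] <- c(1, 3, 5, 3, 1)
  m <- run_activity_map(matrix(trace, 1), 1, lay)
  rf <- detect_run_fields(m, n_shuffles = 1000, seed = 1,
                          params = link_params("simulated"))
  expect_equal(nrow(rf), 1L)
  expect_gte(rf$start_bin, 17)
  expect_lte(rf$end_bin, 23)
  # brute-force oracle: per-bin count of rotations beating the bin
  set.seed(99)
  offs <- sample(seq(ceiling(0.05 * 40), floor(0.95 * 40)), 1000,
                 replace = TRUE)
  ge <- integer(40)
  for (o in offs) ge <- ge + (trace[((seq_len(40) - 1 + o) %% 40) + 1] >= trace)
  oracle <- gridshift:::bin_shuffle_score(trace, 1000, offsets = offs)
  expect_equal(oracle, 1 - ge / 1000)
  expect_true(all(oracle[19:21] >= 0.85))
})

test_that("constant and narrow traces yield no fields", {
  lay <- track_layout(100, 50, bin_size_cm = 2.5)
  m <- run_activity_map(matrix(0.5, 1, 40), 1, lay)
  expect_equal(nrow(detect_run_fields(m, 200, seed = 1)), 0L)
  # 2-bin bump mid-track fails the 3-bin rule
  tr <- rep(0, 40); tr[20:21] <- 5
  m2 <- run_activity_map(matrix(tr, 1), 1, lay)
  expect_equal(nrow(detect_run_fields(m2, 500, seed = 1)), 0L)
  # but 2 bins at the track end are allowed
  tr3 <- rep(0, 40); tr3[39:40] <- 5
  m3 <- run_activity_map(matrix(tr3, 1), 1, lay)
  expect_equal(nrow(detect_run_fields(m3, 500, seed = 1)), 1L)
  expect_error(detect_run_fields(
    run_activity_map(matrix(1, 1, 10), 1,
                     track_layout(25, 10, bin_size_cm = 2.5)), 100),
    "20 bins")
})

make_rf <- function(run, com, start = NULL, width = 4) {
  start <- if (is.null(start)) round(com / 2.5) - width %/% 2 else start
  data.frame(run = run, day = 1L, start_bin = start,
             end_bin = start + width - 1L, com_cm = com,
             width_cm = width * 2.5, mean_value = 1,
             field_id = seq_along(run))
}

test_that("stage 2 links nearest next-run fields within threshold", {
  rf <- make_rf(c(1, 2, 3), c(100, 99, 98))
  segs <- link_adjacent_runs(rf, 28)
  expect_length(segs, 1)
  expect_equal(nrow(segs[[1]]), 3)
  # +10 beats -40 under d = 28
  rf2 <- make_rf(c(1, 2, 2), c(100, 110, 60))
  segs2 <- link_adjacent_runs(rf2, 28)
  runs2 <- sort(vapply(segs2, nrow, 1L), decreasing = TRUE)
  expect_equal(runs2, c(2L, 1L))
  expect_equal(sort(segs2[[which.max(vapply(segs2, nrow, 1L))]]$com_cm),
               c(100, 110))
})

test_that("irresolvable stage-2 ties connect nothing", {
  # two equidistant candidates with identical overlap and width
  rf <- rbind(make_rf(1, 100, start = 38),
              make_rf(2, 90, start = 34),
              make_rf(2, 110, start = 42))
  rf$field_id <- 1:3
  segs <- link_adjacent_runs(rf, 28)
  expect_length(segs, 3)
  expect_true(all(vapply(segs, nrow, 1L) == 1L))
})

test_that("stage 3 bridges gaps up to 7 runs and respects end distances", {
  s1 <- make_rf(1:5, seq(100, 96))
  s2 <- make_rf(8:12, seq(93, 89))
  st <- link_segments(list(s1, s2), d_seg_cm = 28, max_gap = 7)
  expect_length(st$fields, 1)
  expect_equal(nrow(st$fields[[1]]), 10)
  # a gap of 8 runs is too long
  s3 <- make_rf(14:18, seq(88, 84))
  st2 <- link_segments(list(s1, s3), d_seg_cm = 28, max_gap = 7)
  expect_length(st2$fields, 0)
  expect_length(st2$leftover, 2)
})

test_that("stage-3 candidate ties with equal runs, gap and coverage link nothing", {
  s1 <- make_rf(1:4, c(100, 100, 100, 100))
  a <- make_rf(6:8, c(104, 104, 104))
  b <- make_rf(6:8, c(96, 96, 96))
  st <- link_segments(list(s1, a, b), d_seg_cm = 28)
  expect_length(st$fields, 0)
})

test_that("stage 4 merges collinear trends and rejects offset ones", {
  f1 <- make_rf(1:6, 100 - (0:5))
  f2 <- make_rf(10:15, 100 - (9:14))    # same line, 3-run gap
  out <- merge_by_trend(list(f1, f2), d_trend_cm = 10, min_runs = 8)
  expect_length(out, 1)
  expect_equal(nrow(out[[1]]), 12)
  # vertical offset of 2 * d_trend breaks the merge (and both halves are
  # then too short to survive the > 8 runs rule)
  f3 <- make_rf(10:15, 120 - (9:14))
  out2 <- merge_by_trend(list(f1, f3), d_trend_cm = 10, min_runs = 8)
  expect_length(out2, 0)
})

test_that("the > 8 runs inclusion rule is strict", {
  f9 <- make_rf(1:9, 100 - 0.1 * (0:8))
  f8 <- make_rf(1:8, 100 - 0.1 * (0:7))
  expect_length(merge_by_trend(list(f9), 10, min_runs = 8), 1)
  expect_length(merge_by_trend(list(f8), 10, min_runs = 8), 0)
})

test_that("enlarging thresholds never captures fewer runs", {
  g <- fixture_drifting_cell(slope = -0.4, days = 4, runs_per_day = 10,
                             jitter = 2, seed = 11)
  rf <- detect_run_fields(g$map, 300, params = link_params("simulated"),
                          seed = 2)
  runs_at <- function(d) {
    p <- link_params(preset = NULL, d_run_cm = d, d_seg_cm = d,
                     d_trend_cm = d, max_width_cm = Inf)
    fin <- gridshift:::relink_fields(rf, p)
    if (length(fin)) max(vapply(fin, nrow, 1L)) else 0L
  }
  caps <- vapply(c(5, 10, 20, 30), runs_at, 1L)
  expect_true(all(diff(caps) >= 0))
})

test_that("normalized run field count excludes uncovered end stretches", {
  lay <- track_layout(1000, 500, bin_size_cm = 2.5)
  vals <- matrix(1, 3, 400)
  cov <- matrix(TRUE, 3, 400)
  cov[1, 1:80] <- FALSE          # first run covered only from 200 cm
  m <- run_activity_map(vals, c(1, 1, 1), lay, coverage_mask = cov)
  rf <- rbind(make_rf(1, 300), make_rf(1, 500), make_rf(2, 300),
              make_rf(2, 500))
  nc <- normalized_run_field_count(m, rf)
  expect_equal(nc$count_per_cm[1], 2 / 800)
  expect_equal(nc$count_per_cm[2], 2 / 1000)
  expect_equal(nc$count_per_cm[3], 0)
})

test_that("day-level grid classification needs periodicity and contrast", {
  lay <- track_layout(1000, 500, bin_size_cm = 5)   # 200 bins
  centers <- bin_centers(lay)
  # periodic 5-field cell with strong contrast
  trace <- numeric(200)
  for (mu in seq(100, 900, by = 200))
    trace <- trace + exp(-(centers - mu)^2 / (2 * 15^2))
  vals <- matrix(rep(trace, 12), 12, byrow = TRUE)
  m <- run_activity_map(vals, rep(1, 12), lay)
  res <- classify_grid_cell_day(m, n_shuffles = 500, seed = 3)
  expect_true(res$is_grid)
  expect_gte(nrow(res$fields), 5)
  # single-field cell fails (at least two fields required)
  tr1 <- exp(-(centers - 500)^2 / (2 * 15^2))
  m1 <- run_activity_map(matrix(rep(tr1, 12), 12, byrow = TRUE),
                         rep(1, 12), lay)
  res1 <- classify_grid_cell_day(m1, n_shuffles = 500, seed = 3)
  expect_false(res1$is_grid)
  expect_false(res1$criteria["two_fields"])
})

test_that("weak in/out contrast disqualifies a grid cell", {
  lay <- track_layout(1000, 500, bin_size_cm = 5)
  centers <- bin_centers(lay)
  # two clear fields riding on a high baseline: in/out mean ratio < 2
  trace <- 0.8 + exp(-(centers - 300)^2 / (2 * 10^2)) +
    exp(-(centers - 700)^2 / (2 * 10^2))
  m <- run_activity_map(matrix(rep(trace, 12), 12, byrow = TRUE),
                        rep(1, 12), lay)
  res <- classify_grid_cell_day(m, n_shuffles = 500, seed = 3)
  expect_true(res$criteria["two_fields"])
  expect_false(res$criteria["ratio"])
  expect_false(res$is_grid)
})

test_that("cue scores reward template-matched activity", {
  lay <- track_layout(500, c(100, 250, 400), bin_size_cm = 2.5,
                      landmark_width_cm = 10)
  tc <- gridshift:::cue_template(lay)
  res <- cue_score(tc$template, lay, n_shuffles = 100, seed = 1)
  expect_equal(res$score, 1.0)
  expect_true(res$is_cue)
  # constant activity scores 0 by the zero-variance convention
  resc <- cue_score(rep(1, lay$n_bins), lay, n_shuffles = 50, seed = 1)
  expect_equal(resc$score, 0)
  # a circularly displaced copy is realigned to a perfect score
  shifted <- tc$template[c(41:lay$n_bins, 1:40)]
  ress <- cue_score(shifted, lay, n_shuffles = 50, seed = 1)
  expect_equal(ress$score, 1.0)
  expect_error(cue_score(tc$template, track_layout(500, 100,
    bin_size_cm = 2.5, landmark_sides = "right"), side = "left"), "left")
})
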