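test_that("field slope matches closed-form and lm oracles", {
  df <- data.frame(run = 1:4, com_cm = c(10, 9, 8, 7))
  expect_equal(field_slope(df), -1.0)
  expect_equal(field_slope(data.frame(run = 1:5, com_cm = rep(3, 5))), 0)
  df2 <- data.frame(run = 1:4, com_cm = c(10, 8.5, 8, 6.5))
  expect_equal(field_slope(df2), -1.1)                       # closed form
  expect_equal(field_slope(df2), ols_slope_oracle(df2$run, df2$com_cm))
  expect_error(field_slope(data.frame(run = 1, com_cm = 5)), "at least 2")
})

test_that("rotation bootstrap labels monotone and alternating sequences", {
  dec <- data.frame(run = 1:12, com_cm = seq(100, 89))
  expect_equal(classify_shift(dec)$label, "backward")
  # a strictly decreasing sequence attains the rotation minimum slope
  cl <- classify_shift(dec)
  expect_equal(cl$slope_cm_per_run, min(cl$bootstrap), tolerance = 1e-12)
  inc <- data.frame(run = 1:12, com_cm = seq(89, 100))
  expect_equal(classify_shift(inc)$label, "forward")
  alt <- data.frame(run = 1:12, com_cm = 50 + rep(c(1, -1), 6))
  expect_equal(classify_shift(alt)$label, "stationary")
  flat <- data.frame(run = 1:5, com_cm = rep(2, 5))
  expect_equal(classify_shift(flat)$label, "stationary")
})

test_that("classification agrees with the exhaustive rotation oracle", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    runs <- sort(sample(1:40, n))
    com <- round(runif(n, 50, 150), 2)
    df <- data.frame(run = runs, com_cm = com)
    expect_equal(classify_shift(df)$label,
                 classify_shift_oracle(runs, com),
                 info = sprintf("case %d", i))
  }
})

test_that("day fields require three runs and report center, slope, sd", {
  df <- data.frame(run = c(1:4, 5:6, 7:10),
                   day = c(1, 1, 1, 1, 2, 2, 3, 3, 3, 3),
                   com_cm = c(100, 99, 98, 97, 96, 95, 94, 93.5, 93, 92.5))
  dfs <- day_fields(df)
  expect_equal(dfs$day, c(1L, 3L))       # day 2 has only 2 runs
  expect_equal(dfs$center_cm[1], mean(c(100, 99, 98, 97)))
  expect_equal(dfs$slope_cm_per_run[1], -1)
  expect_equal(dfs$com_sd_cm[2], sd(c(94, 93.5, 93, 92.5)))
})

test_that("stabilization metrics report adjacent-day distances only", {
  df <- rbind(data.frame(run = 1:3, day = 1, com_cm = c(100, 100, 100)),
              data.frame(run = 4:6, day = 2, com_cm = c(94, 94, 94)),
              data.frame(run = 10:12, day = 4, com_cm = c(90, 90, 90)))
  sm <- stabilization_metrics(df)
  expect_equal(nrow(sm$adjacent), 1)           # days 2-4 not adjacent
  expect_equal(sm$adjacent$center_distance_cm, 6)
  expect_equal(sm$per_day$com_sd_cm, rep(0, 3))
  expect_equal(sm$per_day$slope_cm_per_run, rep(0, 3))
})

test_that("close/far grouping splits the inter-anchor span from the back anchor", {
  lay <- track_layout(1000, c(200, 400))
  cf <- classify_close_far(NULL, lay, n_bins = 2, location_cm = 240)
  expect_equal(cf$label, "close")
  expect_equal(cf$back_anchor_cm, 200)
  expect_equal(classify_close_far(NULL, lay, 2, location_cm = 310)$label,
               "far")
  # the midpoint belongs to the back-adjacent part
  expect_equal(classify_close_far(NULL, lay, 2, location_cm = 300)$label,
               "close")
  expect_equal(classify_close_far(NULL, lay, 3, location_cm = 340)$label,
               "far2")
  cr <- classify_close_far(NULL, lay, 2, location_cm = 195)
  expect_equal(cr$back_anchor_cm, 0)           # previous span
  expect_false(cr$crossed)
})

test_that("the gaussian null flags piled-up bins and stays calibrated", {
  # piling far from the peak is flagged high
  x <- c(rnorm(60, 50, 6), rep(-45, 18))
  gn <- gaussian_null_pass(x, n_sim = 2000, seed = 3)
  low_bin <- which(gn$lower <= -45 & gn$upper > -45)
  expect_true(gn$significant_high[low_bin])
  expect_equal(attr(gn, "sigma"), diff(range(x)) / 6)
  # data drawn from the null itself flags few bins (the range/6 sd rule is
  # only calibrated once the sample range approaches six sd)
  set.seed(11)
  rates <- replicate(40, {
    y <- rnorm(300, 50, 20)
    g <- gaussian_null_pass(y, n_sim = 400, seed = sample.int(1e6, 1))
    c(mean(g$significant_low), mean(g$significant_high))
  })
  expect_lt(mean(rates), 0.12)
  expect_error(gaussian_null_pass(1), "at least 2")
})

test_that("learning change subtracts the early-window mean", {
  m <- data.frame(day = c(1, 2, 3, 7, 8), value = c(4, 4, 4, 1, 2))
  lc <- learning_change(m)
  expect_equal(lc$delta, c(-3, -2))
  # dataset-2 convention: early window days 1-2
  lc2 <- learning_change(data.frame(day = c(1, 2, 3, 7), value = c(2, 4, 9, 6)),
                         early_days = 1:2)
  expect_equal(lc2$delta, 3)
  expect_error(learning_change(data.frame(day = 7, value = 1)), "early")
})

test_that("reset events need boundary-reaching day fields and enough runs", {
  day_ranges <- data.frame(day = 1:2, first_run = c(1L, 11L),
                           last_run = c(10L, 20L))
  f <- rbind(data.frame(run = 1:10, day = 1,
                        com_cm = c(rep(90, 9), 90)),
             data.frame(run = 11:20, day = 2,
                        com_cm = c(97, rep(96, 9))))
  ev <- detect_reset_events(f, day_ranges, min_runs_per_day = 6)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "regression")
  expect_equal(ev$magnitude_cm, 7)
  # backward displacement is a progression
  f2 <- f; f2$com_cm[11] <- 84
  ev2 <- detect_reset_events(f2, day_ranges, min_runs_per_day = 6)
  expect_equal(ev2$kind, "progression")
  expect_equal(ev2$magnitude_cm, 6)
  # neither field touches its day boundary -> no event
  f3 <- rbind(data.frame(run = 1:7, day = 1, com_cm = rep(90, 7)),
              data.frame(run = 13:20, day = 2, com_cm = rep(95, 8)))
  expect_equal(nrow(detect_reset_events(f3, day_ranges, 6)), 0)
  # too few runs -> no event
  expect_equal(nrow(detect_reset_events(f, day_ranges,
                                        min_runs_per_day = 10)), 0)
})

test_that("reset significance uses a strict same-direction percentile", {
  f <- rbind(data.frame(run = 1:8, day = 1,
                        com_cm = 100 + cumsum(c(0, rep(c(2, -1), length.out = 7)))),
             data.frame(run = 9:16, day = 2,
                        com_cm = 120 + cumsum(c(0, rep(c(2, -1), length.out = 7)))))
  ev <- data.frame(day_from = 1, day_to = 2, displacement_cm = 12,
                   magnitude_cm = 12, kind = "regression")
  rs <- reset_significance(ev, f, pct = 70)
  expect_true(rs$significant)            # 12 cm beats all 2-cm shifts
  # a magnitude exactly at the percentile is NOT significant
  ev2 <- ev; ev2$displacement_cm <- rs$threshold_cm
  ev2$magnitude_cm <- rs$threshold_cm
  expect_false(reset_significance(ev2, f, pct = 70)$significant)
  # empty baseline: flagged, not significant
  fmono <- rbind(data.frame(run = 1:4, day = 1, com_cm = c(100, 99, 98, 97)),
                 data.frame(run = 5:8, day = 2, com_cm = c(105, 104, 103, 102)))
  ev3 <- data.frame(day_from = 1, day_to = 2, displacement_cm = 8,
                    magnitude_cm = 8, kind = "regression")
  rs3 <- reset_significance(ev3, fmono, pct = 70)
  expect_false(rs3$significant)
  expect_true(rs3$empty_baseline)
})

test_that("behavior score combines licking and slowing as printed", {
  expect_equal(behavior_score(0, 50), 0)
  expect_equal(behavior_score(100, 50), 1)
  # good-performer thresholds, unclamped formula value
  expect_equal(behavior_score(22.2, 65.7, clamp = FALSE),
               22.2 / 100 + (65.7 / 100 - 0.5) / 0.52)
  expect_error(behavior_score(120, 50), "0, 100")
})

test_that("shuffled stationary populations show no significant backward excess", {
  set.seed(21)
  cells <- lapply(1:6, function(ci) {
    lapply(1:2, function(fi) {
      com <- 300 * fi + rnorm(12, 0, 2)
      structure(list(cell_id = sprintf("c%d", ci),
                     runs = make_shift_field(com)),
                class = "cross_day_field")
    })
  })
  res <- shuffle_type_fractions(cells, link_params("simulated"),
                                n_shuffle = 40, seed = 2)
  expect_false(res$significant_high["backward"])
  expect_equal(sum(res$observed), 1)
  ok <- stats::complete.cases(res$baseline)
  expect_true(all(abs(rowSums(res$baseline[ok, , drop = FALSE]) - 1) < 1e-9))
})
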