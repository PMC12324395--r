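#' Split a cross-day field into day fields
#'
#' Groups the member run fields by day; day fields need at least
#' \code{min_runs} runs (default 3) to be included. The day-field center is
#' the mean of its run-field COMs.
#'
#' @param field A \code{cross_day_field} or run-field data frame.
#' @param min_runs Minimum runs per day field (default 3).
#' @return Data frame: \code{day, n_runs, center_cm, slope_cm_per_run,
#'   com_sd_cm, first_run, last_run}.
#' @export
day_fields <- function(field, min_runs = 3) {
  df <- if (inherits(field, "cross_day_field")) field$runs else field
  out <- lapply(split(df, df$day), function(d) {
    if (nrow(d) < min_runs) return(NULL)
    data.frame(day = d$day[1], n_runs = nrow(d),
               center_cm = mean(d$com_cm),
               slope_cm_per_run = if (nrow(d) >= 2)
                 unname(com_line(d)["slope"]) else NA_real_,
               com_sd_cm = stats::sd(d$com_cm),
               first_run = min(d$run), last_run = max(d$run))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(day = integer(0), n_runs = integer(0),
                      center_cm = numeric(0), slope_cm_per_run = numeric(0),
                      com_sd_cm = numeric(0), first_run = integer(0),
                      last_run = integer(0))
  rownames(out) <- NULL
  out
}

#' Per-day stabilization metrics of a cross-day field
#'
#' For each day field: the OLS slope of COM on run index, the standard
#' deviation of the member run-field COMs, and (for adjacent day pairs) the
#' absolute distance between day-field centers.
#'
#' @param field A \code{cross_day_field} or run-field data frame.
#' @param min_runs Minimum runs per day field.
#' @return List: \code{per_day} (day-field table) and \code{adjacent}
#'   (data frame \code{day_from, day_to, center_distance_cm}; pairs with a
#'   missing adjacent day are omitted).
#' @export
stabilization_metrics <- function(field, min_runs = 3) {
  dfs <- day_fields(field, min_runs)
  adj <- NULL
  if (nrow(dfs) >= 2) {
    i <- which(diff(dfs$day) == 1L)
    if (length(i))
      adj <- data.frame(day_from = dfs$day[i], day_to = dfs$day[i + 1],
                        center_distance_cm =
                          abs(dfs$center_cm[i + 1] - dfs$center_cm[i]))
  }
  if (is.null(adj))
    adj <- data.frame(day_from = integer(0), day_to = integer(0),
                      center_distance_cm = numeric(0))
  list(per_day = dfs, adjacent = adj)
}

#' Group a backward field as close or far from its back landmark
#'
#' The field location (median of day-field centers) selects the adjacent
#' anchor pair (landmark front edges, with track start and end counting as
#' landmarks); the span between the anchors is split into \code{n_bins}
#' equal parts and the field is labelled by the part containing its
#' location, counted from the back anchor ("close" is nearest the back
#' anchor). A point exactly on a part boundary belongs to the part nearer
#' the back anchor. A location outside the span (field crossed the
#' landmark) is assigned to the closest part and flagged.
#'
#' @param field A \code{cross_day_field} or run-field data frame.
#' @param layout A \code{track_layout}.
#' @param n_bins 2 (close/far) or 3 (close/far1/far2).
#' @param location_cm Optional explicit field location overriding the
#'   median-of-day-centers rule.
#' @return List: \code{label}, \code{bin} (1 = close), \code{back_anchor_cm},
#'   \code{front_anchor_cm}, \code{crossed} (logical flag).
#' @export
classify_close_far <- function(field, layout, n_bins = 2,
                               location_cm = NULL) {
  stopifnot(n_bins %in% c(2, 3))
  if (is.null(location_cm)) {
    dfs <- day_fields(field)
    if (!nrow(dfs)) stop("no day fields with enough runs")
    location_cm <- stats::median(dfs$center_cm)
  }
  a <- anchors(layout)
  k <- findInterval(location_cm, a, rightmost.closed = TRUE)
  k <- min(max(k, 1L), length(a) - 1L)
  back <- a[k]; front <- a[k + 1]
  rel <- (location_cm - back) / (front - back)
  crossed <- rel < 0 || rel > 1
  part <- max(1L, ceiling(pmin(pmax(rel, 0), 1) * n_bins))
  labels <- if (n_bins == 2) c("close", "far") else c("close", "far1", "far2")
  list(label = labels[part], bin = as.integer(part),
       back_anchor_cm = back, front_anchor_cm = front, crossed = crossed)
}

#' Compare landmark-crossing counts with a matched Gaussian null
#'
#' The end percentage distance of a field is its signed relative distance
#' (percent of the inter-landmark span) from the late-learning mean COM to
#' the back landmark, negative when the field crossed it. The observed
#' 20%-binned counts are compared with 20000 same-size samples from a
#' normal distribution whose mean is the empirical PDF peak and whose sd is
#' range/6 (so plus/minus three sd covers over 99% of the range). A bin is
#' significantly low (high) when the observed count falls strictly below
#' the 5th (strictly above the 95th) percentile of the simulated counts.
#'
#' @param end_pcts Per-field end percentage distances (needs >= 2 values).
#' @param n_sim Number of simulated sets (default 20000).
#' @param bin_pct Bin width in percent (default 20).
#' @param seed Integer seed.
#' @return Data frame per bin: \code{lower, upper, count, null_lo, null_hi,
#'   significant_low, significant_high}, plus attributes \code{mu},
#'   \code{sigma}.
#' @export
gaussian_null_pass <- function(end_pcts, n_sim = 20000, bin_pct = 20,
                               seed = 1) {
  end_pcts <- end_pcts[is.finite(end_pcts)]
  if (length(end_pcts) < 2) stop("need at least 2 fields")
  breaks <- seq(floor(min(end_pcts) / bin_pct) * bin_pct,
                ceiling(max(end_pcts) / bin_pct) * bin_pct, by = bin_pct)
  if (length(breaks) < 2) breaks <- c(breaks, breaks + bin_pct)
  counts <- graphics::hist(end_pcts, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  mids <- utils::head(breaks, -1) + bin_pct / 2
  mu <- mids[which.max(counts)]            # peak of the PDF envelope
  sigma <- diff(range(end_pcts)) / 6
  n <- length(end_pcts)
  sim_counts <- with_seed(seed, {
    m <- matrix(0L, n_sim, length(counts))
    for (s in seq_len(n_sim)) {
      x <- stats::rnorm(n, mu, sigma)
      x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)] - 1e-9)
      m[s, ] <- graphics::hist(x, breaks = breaks, plot = FALSE,
                               right = FALSE)$counts
    }
    m
  })
  lo <- apply(sim_counts, 2, pctile, 0.05)
  hi <- apply(sim_counts, 2, pctile, 0.95)
  out <- data.frame(lower = utils::head(breaks, -1),
                    upper = breaks[-1], count = counts,
                    null_lo = lo, null_hi = hi,
                    significant_low = counts < lo,
                    significant_high = counts > hi)
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Late-learning change of a per-day metric
#'
#' Subtracts the mean of the early-learning window from each late-day value
#' (one delta per late day). The dataset-2 convention uses days 1-2 as the
#' early window; dataset 1 and simulated data use days 1-3. The late window
#' is days 7-10 for all datasets.
#'
#' @param metric_by_day Named numeric vector (names = day numbers) or data
#'   frame with columns \code{day}, \code{value}.
#' @param early_days Early window (default 1:3).
#' @param late_days Late window (default 7:10).
#' @return Data frame \code{day, delta} with one row per late day present.
#' @export
learning_change <- function(metric_by_day, early_days = 1:3,
                            late_days = 7:10) {
  if (is.data.frame(metric_by_day)) {
    day <- metric_by_day$day; value <- metric_by_day$value
  } else {
    day <- as.integer(names(metric_by_day)); value <- unname(metric_by_day)
  }
  early <- value[day %in% early_days]
  if (!length(early) || all(!is.finite(early))) stop("empty early window")
  base <- mean(early, na.rm = TRUE)
  sel <- day %in% late_days & is.finite(value)
  data.frame(day = day[sel], delta = value[sel] - base)
}
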