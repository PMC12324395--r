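#' Detect regression and progression events at day boundaries
#'
#' An event occurs between day fields on adjacent days when (a) the earlier
#' day field's last run reaches the last run of its day, or (b) the later
#' day field's first run is the first run of its day; both day fields must
#' have strictly more than \code{min_runs_per_day} runs. Regression is a
#' forward displacement of the field across the boundary (the next day's
#' first run-field COM is ahead of the previous day's last run-field COM);
#' progression is a backward displacement.
#'
#' @param field A \code{cross_day_field} or run-field data frame.
#' @param day_ranges Data frame from \code{\link{day_run_ranges}} giving
#'   each day's first and last global run index.
#' @param min_runs_per_day Run-count minimum (strict); presets: 6 for
#'   dataset 1, 3 for dataset 2, 9 for the full simulated schedule.
#' @return Data frame: \code{day_from, day_to, displacement_cm,
#'   magnitude_cm, kind} ("regression" or "progression").
#' @export
detect_reset_events <- function(field, day_ranges, min_runs_per_day = 6) {
  df <- if (inherits(field, "cross_day_field")) field$runs else field
  days <- sort(unique(df$day))
  out <- list()
  for (d in days) {
    if (!((d + 1) %in% days)) next
    a <- df[df$day == d, , drop = FALSE]
    b <- df[df$day == d + 1, , drop = FALSE]
    if (nrow(a) <= min_runs_per_day || nrow(b) <= min_runs_per_day) next
    ra <- day_ranges[day_ranges$day == d, ]
    rb <- day_ranges[day_ranges$day == d + 1, ]
    if (!nrow(ra) || !nrow(rb)) next
    cond_a <- max(a$run) == ra$last_run
    cond_b <- min(b$run) == rb$first_run
    if (!cond_a && !cond_b) next
    last_com <- a$com_cm[which.max(a$run)]
    first_com <- b$com_cm[which.min(b$run)]
    disp <- first_com - last_com
    out[[length(out) + 1L]] <- data.frame(
      day_from = d, day_to = d + 1, displacement_cm = disp,
      magnitude_cm = abs(disp),
      kind = if (disp >= 0) "regression" else "progression")
  }
  if (!length(out))
    return(data.frame(day_from = integer(0), day_to = integer(0),
                      displacement_cm = numeric(0), magnitude_cm = numeric(0),
                      kind = character(0)))
  do.call(rbind, out)
}

#' Significance of a reset event against within-day shifts
#'
#' The baseline is the set of adjacent-run COM shifts inside the two
#' participating day fields that point in the same direction as the event.
#' The event is significant iff its magnitude strictly exceeds the
#' \code{pct}-th percentile of the baseline. An empty baseline yields
#' \code{FALSE} with a flag.
#'
#' @param event One row of \code{\link{detect_reset_events}} output.
#' @param field The parent \code{cross_day_field} or run-field data frame.
#' @param pct Percentile threshold; presets: 85 for dataset 2, 70 for
#'   dataset 1 and simulated data.
#' @return List: \code{significant}, \code{threshold_cm},
#'   \code{n_baseline}, \code{empty_baseline}.
#' @export
reset_significance <- function(event, field, pct = 70) {
  df <- if (inherits(field, "cross_day_field")) field$runs else field
  shifts <- c()
  for (d in c(event$day_from, event$day_to)) {
    a <- df[df$day == d, , drop = FALSE]
    a <- a[order(a$run), , drop = FALSE]
    if (nrow(a) >= 2) shifts <- c(shifts, diff(a$com_cm))
  }
  same_dir <- if (event$displacement_cm >= 0) shifts[shifts > 0]
    else shifts[shifts < 0]
  if (!length(same_dir))
    return(list(significant = FALSE, threshold_cm = NA_real_,
                n_baseline = 0L, empty_baseline = TRUE))
  thr <- pctile(abs(same_dir), pct / 100)
  list(significant = event$magnitude_cm > thr, threshold_cm = thr,
       n_baseline = length(same_dir), empty_baseline = FALSE)
}

#' Magnitude-scaled regression-significance percentile
#'
#' Transfers a percentile threshold between datasets in proportion to their
#' mean forward-regression magnitudes: \code{pct * (mag_target / mag_source)}.
#' With the published values (85th percentile, 9.503 cm vs 10.984 cm mean
#' forward regression) this gives 73.539, rounded to the 70th percentile in
#' practice.
#'
#' @param pct_source Source-dataset percentile (e.g. 85).
#' @param mag_target Mean forward-regression magnitude of the target
#'   dataset (cm).
#' @param mag_source Mean forward-regression magnitude of the source
#'   dataset (cm).
#' @return Scaled percentile.
#' @examples
#' reset_percentile_scaled(85, 9.503, 10.984)
#' @export
reset_percentile_scaled <- function(pct_source, mag_target, mag_source) {
  stopifnot(pct_source > 0, mag_target > 0, mag_source > 0)
  pct_source * (mag_target / mag_source)
}

#' Behavioral learning score
#'
#' Combines predictive licking (PL, percent of pre-reward licks) and
#' predictive slowing (PS, percentile of pre-reward deceleration) into one
#' score: \code{PL/100 + (PS/100 - 0.5)/0.52}, optionally clamped to [0, 1]
#' for reporting. A mouse counts as a good performer when PL exceeds 22.2
#' percent or PS exceeds the 65.7th percentile.
#'
#' @param PL Predictive licking in percent, in [0, 100].
#' @param PS Predictive slowing percentile, in [0, 100].
#' @param clamp Clamp the reported score to [0, 1] (default TRUE).
#' @return Numeric score.
#' @examples
#' behavior_score(22.2, 65.7)
#' @export
behavior_score <- function(PL, PS, clamp = TRUE) {
  if (any(PL < 0 | PL > 100) || any(PS < 0 | PS > 100))
    stop("PL and PS must lie in [0, 100]")
  s <- PL / 100 + (PS / 100 - 0.5) / 0.52
  if (clamp) s <- pmin(pmax(s, 0), 1)
  s
}
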