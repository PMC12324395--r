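#' Slope of a cross-day field
#'
#' Ordinary least squares of run-field COM on global run index, in cm/run.
#' Strictly non-shifting fields have slope 0; backward-shifting fields have
#' negative slope.
#'
#' @param field A \code{cross_day_field} or a data frame with columns
#'   \code{run} and \code{com_cm}.
#' @return Slope in cm/run.
#' @export
field_slope <- function(field) {
  df <- if (inherits(field, "cross_day_field")) field$runs else field
  if (nrow(df) < 2) stop("slope needs at least 2 run fields")
  unname(com_line(df)["slope"])
}

# Bootstrap slope distribution from all circular rotations of the sorted
# COM sequence (run indices fixed). Sorting the COMs (descending) first
# arranges the maximal possible shift; rotations of that arrangement span
# the achievable slope range.
rotation_slopes <- function(run, com) {
  n <- length(com)
  sorted <- sort(com, decreasing = TRUE)
  vapply(seq_len(n) - 1L, function(k) {
    rot <- sorted[((seq_len(n) - 1L + k) %% n) + 1L]
    stats::cov(run, rot) / stats::var(run)
  }, 1)
}

#' Classify the shift direction of a cross-day field
#'
#' The observed OLS slope is compared with a bootstrap distribution built by
#' sorting the run-field COMs (descending, the maximal-shift arrangement)
#' and computing the slope of every circular rotation of that sequence over
#' the fixed run indices. The field is backward if its slope is at or below
#' the 10th percentile of the bootstrap, forward if at or above the 90th,
#' otherwise stationary. All-equal COMs give a degenerate bootstrap and are
#' labelled stationary.
#'
#' @param field A \code{cross_day_field} or data frame with \code{run},
#'   \code{com_cm}.
#' @return List: \code{label} (\code{"backward"}, \code{"forward"} or
#'   \code{"stationary"}), \code{slope_cm_per_run}, \code{bootstrap}
#'   (rotation slopes), \code{lo}, \code{hi} (the percentile bounds).
#' @export
classify_shift <- function(field) {
  df <- if (inherits(field, "cross_day_field")) field$runs else field
  if (nrow(df) < 2) stop("classification needs at least 2 run fields")
  slope <- field_slope(df)
  if (length(unique(df$com_cm)) == 1L)
    return(list(label = "stationary", slope_cm_per_run = slope,
                bootstrap = rep(0, nrow(df)), lo = 0, hi = 0))
  boot <- rotation_slopes(df$run, df$com_cm)
  lo <- pctile(boot, 0.10)
  hi <- pctile(boot, 0.90)
  label <- if (slope <= lo) "backward" else if (slope >= hi) "forward"
    else "stationary"
  list(label = label, slope_cm_per_run = slope, bootstrap = boot,
       lo = lo, hi = hi)
}

shift_fractions <- function(fields) {
  labs <- vapply(fields, function(f) classify_shift(f)$label, "")
  n <- length(labs)
  c(backward = mean(labs == "backward"),
    forward = mean(labs == "forward"),
    stationary = mean(labs == "stationary"))
}

#' Observed vs baseline shift-type fractions
#'
#' Shuffles run fields within each detected cross-day field (permuting
#' which run each run field occupies), re-runs the linking stages and the
#' shift classification, and recomputes the fraction of backward, forward
#' and stationary fields per shuffle. The observed fraction of a type is
#' significantly high (low) if it is at or above the 95th (at or below the
#' 5th) percentile of the baseline distribution.
#'
#' @param cells List of per-cell field lists (each element a list of
#'   \code{cross_day_field}s for one cell).
#' @param params \code{link_params} used for re-linking.
#' @param n_shuffle Number of shuffles (default 100).
#' @param seed Integer seed.
#' @return List: \code{observed} (named fractions), \code{baseline}
#'   (n_shuffle x 3 matrix), \code{significant_high},
#'   \code{significant_low} (named logicals).
#' @export
shuffle_type_fractions <- function(cells, params = link_params("simulated"),
                                   n_shuffle = 100, seed = 1) {
  all_fields <- unlist(cells, recursive = FALSE)
  stopifnot(length(all_fields) > 0)
  observed <- shift_fractions(all_fields)
  baseline <- with_seed(seed, {
    t(vapply(seq_len(n_shuffle), function(s) {
      shuf_cells <- lapply(cells, function(fl) {
        rf <- do.call(rbind, lapply(fl, function(f) {
          df <- f$runs
          df$run <- sample(df$run)     # permute run order within the field
          df[order(df$run), , drop = FALSE]
        }))
        relink_fields(rf, params)
      })
      fl <- unlist(shuf_cells, recursive = FALSE)
      if (!length(fl)) return(c(backward = NA, forward = NA, stationary = NA))
      shift_fractions(fl)
    }, c(backward = 0, forward = 0, stationary = 0)))
  })
  ok <- stats::complete.cases(baseline)
  bl <- baseline[ok, , drop = FALSE]
  hi <- vapply(names(observed), function(k)
    observed[k] >= pctile(bl[, k], 0.95), TRUE)
  lo <- vapply(names(observed), function(k)
    observed[k] <= pctile(bl[, k], 0.05), TRUE)
  list(observed = observed, baseline = baseline,
       significant_high = hi, significant_low = lo)
}
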