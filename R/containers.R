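#' Track layout for a virtual linear track
#'
#' Describes the geometry shared by all analyses: track length, the front
#' edges of the visual landmarks, an optional reward span, and the spatial
#' bin size. The start and end of the track count as landmarks, so the
#' effective anchor set is \code{c(0, landmark_edges_cm, length_cm)}.
#'
#' All coordinates are in cm from the track start. Bins are half-open
#' intervals \code{[k*bin, (k+1)*bin)}; centers of mass are reported at bin
#' centers.
#'
#' @param length_cm Positive track length in cm; must be an integer multiple
#'   of \code{bin_size_cm} (tolerance 1e-9).
#' @param landmark_edges_cm Strictly increasing landmark front-edge
#'   positions, all inside \code{(0, length_cm)}.
#' @param reward_span_cm Optional length-2 numeric, the closed reward
#'   interval in cm.
#' @param bin_size_cm Positive spatial bin size in cm (2.5 for run-by-run
#'   analyses, 5 for day-level classification, 1 for phase trajectories).
#' @param landmark_width_cm Physical landmark width used by cue templates.
#' @param landmark_sides Optional character vector (\code{"left"},
#'   \code{"right"} or \code{"both"}) per landmark; defaults to
#'   \code{"both"}.
#' @return An object of class \code{track_layout}.
#' @examples
#' lay <- track_layout(1000, c(120, 240, 360, 480, 600, 740, 863, 909))
#' anchors(lay)
#' @export
track_layout <- function(length_cm, landmark_edges_cm,
                         reward_span_cm = NULL, bin_size_cm = 2.5,
                         landmark_width_cm = 10,
                         landmark_sides = NULL) {
  stopifnot(is.numeric(length_cm), length(length_cm) == 1L, length_cm > 0,
            is.numeric(bin_size_cm), bin_size_cm > 0)
  landmark_edges_cm <- as.numeric(landmark_edges_cm)
  if (length(landmark_edges_cm) > 0) {
    if (any(diff(landmark_edges_cm) <= 0))
      stop("landmark_edges_cm must be strictly increasing")
    if (any(landmark_edges_cm <= 0) || any(landmark_edges_cm >= length_cm))
      stop("landmark_edges_cm must lie strictly inside (0, length_cm)")
  }
  n_bins <- length_cm / bin_size_cm
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("length_cm must be an integer multiple of bin_size_cm")
  if (!is.null(reward_span_cm)) {
    stopifnot(length(reward_span_cm) == 2L, reward_span_cm[1] < reward_span_cm[2])
  }
  if (is.null(landmark_sides)) {
    landmark_sides <- rep("both", length(landmark_edges_cm))
  }
  stopifnot(length(landmark_sides) == length(landmark_edges_cm),
            all(landmark_sides %in% c("left", "right", "both")))
  structure(list(length_cm = length_cm,
                 landmark_edges_cm = landmark_edges_cm,
                 reward_span_cm = reward_span_cm,
                 bin_size_cm = bin_size_cm,
                 landmark_width_cm = landmark_width_cm,
                 landmark_sides = landmark_sides,
                 n_bins = as.integer(round(n_bins))),
            class = "track_layout")
}

#' Effective anchor set of a track layout
#'
#' Landmark front edges plus the start and end of the track, which count as
#' landmarks.
#' @param layout A \code{track_layout}.
#' @return Sorted numeric vector of anchor positions in cm.
#' @export
anchors <- function(layout) {
  stopifnot(inherits(layout, "track_layout"))
  c(0, layout$landmark_edges_cm, layout$length_cm)
}

#' Bin centers of a track layout
#' @param layout A \code{track_layout}.
#' @param bin_size_cm Optional override of the layout's bin size.
#' @return Numeric vector of bin-center positions in cm.
#' @export
bin_centers <- function(layout, bin_size_cm = NULL) {
  bs <- if (is.null(bin_size_cm)) layout$bin_size_cm else bin_size_cm
  n <- round(layout$length_cm / bs)
  (seq_len(n) - 0.5) * bs
}

#' @export
print.track_layout <- function(x, ...) {
  cat(sprintf("<track_layout> %g cm, %d landmarks, %g cm bins (%d bins)\n",
              x$length_cm, length(x$landmark_edges_cm), x$bin_size_cm,
              x$n_bins))
  invisible(x)
}

#' Run-by-run spatial activity map of one cell
#'
#' The universal input of the pipeline: a runs x track-bins matrix of
#' non-negative activity values (e.g. spatially binned dF/F), one row per
#' traversal, with per-run day labels. Rows are ordered by
#' \code{(day, within-day run order)} and \code{run_index} is a strictly
#' increasing global run counter. Bins without data are marked by the
#' coverage mask and carry \code{NA} in \code{values} (a sentinel distinct
#' from 0); covered bins must be finite and non-negative.
#'
#' @param values Numeric runs x bins matrix.
#' @param day_of_run Integer vector (one per run), non-decreasing, >= 1.
#' @param layout A \code{track_layout} whose bin count matches
#'   \code{ncol(values)}.
#' @param cell_id Character scalar.
#' @param run_index Optional strictly increasing integer run counter
#'   (default \code{seq_len(nrow(values))}).
#' @param coverage_mask Optional logical matrix of the same shape; defaults
#'   to \code{!is.na(values)}.
#' @return An object of class \code{run_activity_map}.
#' @export
run_activity_map <- function(values, day_of_run, layout, cell_id = "cell",
                             run_index = NULL, coverage_mask = NULL) {
  stopifnot(is.matrix(values), inherits(layout, "track_layout"))
  if (ncol(values) != layout$n_bins)
    stop(sprintf("values has %d bins but layout expects %d",
                 ncol(values), layout$n_bins))
  n_runs <- nrow(values)
  day_of_run <- as.integer(day_of_run)
  stopifnot(length(day_of_run) == n_runs, all(day_of_run >= 1L))
  if (is.null(run_index)) run_index <- seq_len(n_runs)
  run_index <- as.integer(run_index)
  stopifnot(length(run_index) == n_runs)
  ord <- order(day_of_run, run_index)
  if (any(ord != seq_len(n_runs))) {
    warning("runs out of (day, run) order; re-sorting")
    values <- values[ord, , drop = FALSE]
    day_of_run <- day_of_run[ord]
    run_index <- run_index[ord]
    if (!is.null(coverage_mask)) coverage_mask <- coverage_mask[ord, , drop = FALSE]
  }
  if (any(diff(run_index) <= 0)) stop("run_index must be strictly increasing")
  if (any(diff(day_of_run) < 0)) stop("day_of_run must be non-decreasing")
  # plain NA marks an uncovered bin; NaN is invalid data and stays covered
  # so validation can reject it
  if (is.null(coverage_mask)) coverage_mask <- !(is.na(values) & !is.nan(values))
  stopifnot(is.logical(coverage_mask), all(dim(coverage_mask) == dim(values)))
  bad <- coverage_mask & !is.finite(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    stop(sprintf("non-finite values at covered bins: %s",
                 paste(sprintf("(%s, run %d, bin %d)", cell_id,
                               run_index[idx[, 1]], idx[, 2])[seq_len(min(5, nrow(idx)))],
                       collapse = ", ")))
  }
  if (any(values[coverage_mask] < 0)) stop("activity values must be non-negative")
  values[!coverage_mask] <- NA_real_
  structure(list(cell_id = as.character(cell_id), values = values,
                 day_of_run = day_of_run, run_index = run_index,
                 layout = layout, coverage_mask = coverage_mask),
            class = "run_activity_map")
}

#' @export
print.run_activity_map <- function(x, ...) {
  cat(sprintf("<run_activity_map> cell %s: %d runs x %d bins, days %d-%d\n",
              x$cell_id, nrow(x$values), ncol(x$values),
              min(x$day_of_run), max(x$day_of_run)))
  invisible(x)
}

#' Per-day first and last global run index of a map
#' @param map A \code{run_activity_map}.
#' @return Data frame with columns \code{day}, \code{first_run},
#'   \code{last_run}.
#' @export
day_run_ranges <- function(map) {
  days <- sort(unique(map$day_of_run))
  data.frame(day = days,
             first_run = vapply(days, function(d) min(map$run_index[map$day_of_run == d]), 1L),
             last_run = vapply(days, function(d) max(map$run_index[map$day_of_run == d]), 1L))
}
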