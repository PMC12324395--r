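#' Linking parameters for cross-day field tracking
#'
#' Distance thresholds (cm) for the three linking stages, the maximum run
#' gap, the run-field width ceiling and the minimum run count of a final
#' cross-day field. Presets reproduce the published analysis settings for
#' the two imaging datasets and for simulated data.
#'
#' @param preset One of \code{"dataset1"}, \code{"dataset2"},
#'   \code{"simulated"} (the published presets), \code{"model"} (thresholds
#'   suited to the scaled circuit model's faster per-run drift), or
#'   \code{NULL} for fully manual values.
#' @param d_run_cm Stage-2 COM distance threshold.
#' @param d_seg_cm Stage-3 segment-end distance threshold.
#' @param d_trend_cm Stage-4 trend-extension threshold.
#' @param max_gap_runs Maximum run gap bridged by Stages 3-4.
#' @param max_width_cm Run fields wider than this are dropped at Stage 1.
#' @param min_runs Final fields must have strictly more than this many runs.
#' @return A \code{link_params} list.
#' @export
link_params <- function(preset = c("dataset1", "dataset2", "simulated",
                                   "model"),
                        d_run_cm = NULL, d_seg_cm = NULL, d_trend_cm = NULL,
                        max_gap_runs = 7, max_width_cm = NULL, min_runs = 8) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    p <- switch(preset,
                dataset1 = list(28, 28, 28, 95),
                dataset2 = list(32, 38, 34, 150),
                simulated = list(10, 10, 10, Inf),
                model = list(30, 30, 30, Inf))
    if (is.null(d_run_cm)) d_run_cm <- p[[1]]
    if (is.null(d_seg_cm)) d_seg_cm <- p[[2]]
    if (is.null(d_trend_cm)) d_trend_cm <- p[[3]]
    if (is.null(max_width_cm)) max_width_cm <- p[[4]]
  }
  stopifnot(d_run_cm > 0, d_seg_cm > 0, d_trend_cm > 0, max_width_cm > 0)
  structure(list(d_run_cm = d_run_cm, d_seg_cm = d_seg_cm,
                 d_trend_cm = d_trend_cm, max_gap_runs = max_gap_runs,
                 max_width_cm = max_width_cm, min_runs = min_runs),
            class = "link_params")
}

#' Center of mass of a field
#'
#' Activity-weighted mean position, \code{sum(value * center) / sum(value)}.
#' @param field_values Non-negative per-bin activity (at least one positive).
#' @param bin_centers_cm Bin-center positions in cm.
#' @return COM in cm.
#' @examples
#' compute_com(c(1, 3), c(1.25, 3.75))
#' @export
compute_com <- function(field_values, bin_centers_cm) {
  stopifnot(length(field_values) == length(bin_centers_cm))
  s <- sum(field_values)
  if (!is.finite(s) || s <= 0) stop("COM undefined: no positive values")
  sum(field_values * bin_centers_cm) / s
}

# 1 - p per bin for one run: p = fraction of circular rotations whose value
# at the bin is >= the observed value. Rotation offsets are drawn uniformly
# (with replacement) from [0.05 N, 0.95 N] samples.
bin_shuffle_score <- function(trace, n_shuffles, offsets = NULL) {
  n <- length(trace)
  if (is.null(offsets))
    offsets <- sample(seq(ceiling(0.05 * n), floor(0.95 * n)), n_shuffles,
                      replace = TRUE)
  rotation_score_cpp(trace, as.integer(offsets))
}

# Maximal contiguous blocks of `flag` with the end-relaxed length rule:
# >= min_len bins, or >= end_min_len if the block touches either track end.
contiguous_blocks <- function(flag, min_len = 3L, end_min_len = 2L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- list()
  n <- length(flag)
  for (i in keep) {
    len <- r$lengths[i]
    at_end <- starts[i] == 1L || ends[i] == n
    if (len >= min_len || (at_end && len >= end_min_len))
      out[[length(out) + 1L]] <- c(starts[i], ends[i])
  }
  out
}

#' Detect run fields by a circular-rotation shuffle test (Stage 1)
#'
#' Per run, each bin's activity is compared against \code{n_shuffles}
#' circular rotations of that run's own binned trace (offsets uniform on
#' [0.05 N, 0.95 N] samples, drawn with replacement). A run field is a
#' maximal block of at least 3 adjacent bins (2 at the track ends) whose
#' \code{1 - p >= crit}; fields wider than \code{params$max_width_cm} are
#' dropped. Uncovered bins never enter a field.
#'
#' @param map A \code{run_activity_map} (2.5-cm bins in the published
#'   convention; at least 20 bins).
#' @param n_shuffles Number of rotations (default 1000).
#' @param crit Significance criterion on \code{1 - p} (default 0.85).
#' @param params A \code{link_params}.
#' @param seed Integer seed for the rotation offsets.
#' @return Data frame of run fields: \code{run, day, start_bin, end_bin,
#'   com_cm, width_cm, mean_value, field_id}.
#' @export
detect_run_fields <- function(map, n_shuffles = 1000, crit = 0.85,
                              params = link_params("simulated"), seed = 1) {
  stopifnot(inherits(map, "run_activity_map"))
  nb <- ncol(map$values)
  if (nb < 20) stop("run shorter than 20 bins rejected")
  centers <- bin_centers(map$layout)
  bs <- map$layout$bin_size_cm
  out <- list()
  with_seed(seed, {
    for (r in seq_len(nrow(map$values))) {
      trace <- map$values[r, ]
      cov <- map$coverage_mask[r, ]
      tr0 <- ifelse(cov, trace, 0)
      if (all(tr0 == 0)) next
      score <- bin_shuffle_score(tr0, n_shuffles)
      flag <- (score >= crit) & cov & tr0 > 0
      blocks <- contiguous_blocks(flag)
      for (b in blocks) {
        width <- (b[2] - b[1] + 1) * bs
        if (width > params$max_width_cm) next
        idx <- b[1]:b[2]
        out[[length(out) + 1L]] <- data.frame(
          run = map$run_index[r], day = map$day_of_run[r],
          start_bin = b[1], end_bin = b[2],
          com_cm = compute_com(tr0[idx], centers[idx]),
          width_cm = width, mean_value = mean(tr0[idx]))
      }
    }
  })
  if (!length(out))
    return(data.frame(run = integer(0), day = integer(0),
                      start_bin = integer(0), end_bin = integer(0),
                      com_cm = numeric(0), width_cm = numeric(0),
                      mean_value = numeric(0), field_id = integer(0)))
  df <- do.call(rbind, out)
  df$field_id <- seq_len(nrow(df))
  df
}
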