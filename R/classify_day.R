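# 3-bin Gaussian smoothing (sd = 1 bin) used for day-level classification.
smooth3 <- function(x) {
  k <- stats::dnorm(-1:1)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(x[1], x, x[n])
  k[1] * xp[1:n] + k[2] * xp[2:(n + 1)] + k[3] * xp[3:(n + 2)]
}

#' Classify a cell as a grid cell within a single day
#'
#' Works on the run-averaged, 3-bin-Gaussian-smoothed activity trace
#' (5-cm bins in the published convention). Day fields are blocks of at
#' least 3 adjacent bins (2 at the ends) whose activity beats at least 80%
#' of 1000 circular rotations, and at least 10% of runs must show a
#' transient inside the field. The cell is a grid cell iff it has (a) at
#' least two fields, (b) more than L/(5w) in/out transitions (w = mean field
#' width), (c) widest field narrower than 5w, (d) at least 30% of bins
#' assigned in- or out-of-field, and (e) in/out mean activity ratio >= 2.
#'
#' @param day_map A \code{run_activity_map} restricted to one day.
#' @param n_shuffles Number of rotations (default 1000).
#' @param crit Criterion on 1 - p for in-field bins (default 0.8); bins with
#'   1 - p <= 1 - crit count as out-of-field, the rest are unassigned.
#' @param seed Integer seed.
#' @return List: \code{is_grid}, \code{fields} (data frame), and
#'   \code{criteria} (named logical vector of the five tests).
#' @export
classify_grid_cell_day <- function(day_map, n_shuffles = 1000, crit = 0.8,
                                   seed = 1) {
  stopifnot(inherits(day_map, "run_activity_map"))
  vals <- day_map$values
  vals[!day_map$coverage_mask] <- NA
  avg <- colMeans(vals, na.rm = TRUE)
  avg[!is.finite(avg)] <- 0
  tr <- smooth3(avg)
  L <- day_map$layout$length_cm
  bs <- day_map$layout$bin_size_cm
  centers <- bin_centers(day_map$layout)
  score <- with_seed(seed, bin_shuffle_score(tr, n_shuffles))
  infield <- score >= crit & tr > 0
  outfield <- score <= (1 - crit)
  blocks <- contiguous_blocks(infield)
  # transient requirement: >= 10% of runs active inside the field
  keep <- vapply(blocks, function(b) {
    sub <- day_map$values[, b[1]:b[2], drop = FALSE]
    active <- apply(sub, 1, function(v) any(is.finite(v) & v > 0))
    mean(active) >= 0.1
  }, TRUE)
  blocks <- blocks[keep]
  fields <- if (length(blocks)) do.call(rbind, lapply(blocks, function(b) {
    idx <- b[1]:b[2]
    data.frame(start_bin = b[1], end_bin = b[2],
               width_cm = length(idx) * bs,
               com_cm = compute_com(tr[idx], centers[idx]),
               peak_cm = centers[idx][which.max(tr[idx])])
  })) else data.frame(start_bin = integer(0), end_bin = integer(0),
                      width_cm = numeric(0), com_cm = numeric(0),
                      peak_cm = numeric(0))
  crits <- c(two_fields = FALSE, transitions = FALSE, widest = FALSE,
             assigned = FALSE, ratio = FALSE)
  if (nrow(fields) >= 2) {
    crits["two_fields"] <- TRUE
    w <- mean(fields$width_cm)
    in_bins <- unlist(lapply(blocks, function(b) b[1]:b[2]))
    state <- rep(NA, length(tr))
    state[in_bins] <- 1
    state[outfield & !(seq_along(tr) %in% in_bins)] <- 0
    st <- state[!is.na(state)]
    transitions <- sum(diff(st) != 0)
    crits["transitions"] <- transitions > L / (5 * w)
    crits["widest"] <- max(fields$width_cm) < 5 * w
    crits["assigned"] <- mean(!is.na(state)) >= 0.3
    out_mean <- mean(tr[state %in% 0])
    in_mean <- mean(tr[in_bins])
    crits["ratio"] <- is.finite(out_mean) && out_mean > 0 &&
      (in_mean / out_mean) >= 2
  }
  list(is_grid = all(crits), fields = fields, criteria = crits)
}

# Cue template over track bins: 1 inside landmark spans, 0 elsewhere; zones
# are the spans expanded by half the landmark width on each side.
cue_template <- function(layout, edges = NULL, side = "both") {
  if (is.null(edges)) {
    sel <- if (side == "both") rep(TRUE, length(layout$landmark_edges_cm))
      else layout$landmark_sides %in% c(side, "both")
    edges <- layout$landmark_edges_cm[sel]
  }
  w <- layout$landmark_width_cm
  centers <- bin_centers(layout)
  tmpl <- numeric(length(centers))
  zones <- list()
  for (e in edges) {
    tmpl[centers >= e & centers <= e + w] <- 1
    z0 <- max(0, e - w / 2); z1 <- min(layout$length_cm, e + 1.5 * w)
    zones[[length(zones) + 1L]] <- which(centers >= z0 & centers <= z1)
  }
  list(template = tmpl, zones = zones, edges = edges)
}

# Correlation with the constant-trace convention: 0 when either side has
# zero variance.
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

cue_score_once <- function(activity, tc) {
  n <- length(activity)
  best <- -Inf; best_shift <- 0L
  for (s in 0:(n - 1)) {
    shifted <- activity[((seq_len(n) - 1 + s) %% n) + 1]
    r <- safe_cor(shifted, tc$template)
    if (r > best) { best <- r; best_shift <- s }
  }
  shifted <- activity[((seq_len(n) - 1 + best_shift) %% n) + 1]
  mean(vapply(tc$zones, function(z) safe_cor(shifted[z], tc$template[z]), 1))
}

#' Cue score of a day-averaged activity trace
#'
#' The activity is circularly shifted to best match a cue template (ones
#' inside landmark spans); the score is the mean, over landmark zones
#' (landmark expanded by half its width on each side), of the correlation
#' between the aligned activity and the template. Shuffled scores randomize
#' the landmark locations in the template; the cell is a cue cell if its
#' score exceeds the 80th percentile of the (caller-pooled) shuffles.
#'
#' @param activity Day-averaged binned activity vector.
#' @param layout A \code{track_layout} with matching bin count.
#' @param side \code{"left"}, \code{"right"} or \code{"both"}.
#' @param n_shuffles Number of template randomizations (default 200).
#' @param seed Integer seed.
#' @return List: \code{score}, \code{shuffle_scores}, \code{is_cue}
#'   (against this cell's own shuffles at the 80th percentile).
#' @export
cue_score <- function(activity, layout, side = "both", n_shuffles = 200,
                      seed = 1) {
  stopifnot(length(activity) == layout$n_bins)
  tc <- cue_template(layout, side = side)
  if (!length(tc$edges)) stop(sprintf("no landmarks of side '%s'", side))
  score <- cue_score_once(activity, tc)
  w <- layout$landmark_width_cm
  shuffle_scores <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    e <- sort(stats::runif(length(tc$edges), 0, layout$length_cm - w))
    cue_score_once(activity, cue_template(layout, edges = e))
  }, 1))
  list(score = score, shuffle_scores = shuffle_scores,
       is_cue = score > pctile(shuffle_scores, 0.8))
}
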