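# Unwrap a phase series so adjacent differences lie in (-pi, pi].
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  adj <- -2 * pi * round(d / (2 * pi))
  d2 <- d + adj
  fix <- d2 <= -pi          # boundary: move (-pi] up to the (+pi] side
  d2[fix] <- d2[fix] + 2 * pi
  cumsum(c(p[1], d2))
}

#' Shear rhombus bin coordinates
#'
#' Maps integer phase-bin coordinates (m, n) onto the rhombus:
#' \code{s1 = m + n/2}, \code{s2 = sqrt(3)/2 * m}.
#' @param m,n Non-negative integer coordinates.
#' @return Two-column matrix \code{(s1, s2)}.
#' @examples
#' shear_bins(1, 1)
#' @export
shear_bins <- function(m, n) {
  cbind(s1 = m + n / 2, s2 = sqrt(3) / 2 * m)
}

# Shear phase-trajectory coordinates onto the rhombus frame.
shear_phase <- function(psi1, psi2) {
  cbind(psi1 + psi2 / 2, sqrt(3) / 2 * psi2)
}

#' Population phase trajectory of a co-modular module
#'
#' The rate-weighted circular mean of the per-cell phases as a function of
#' track position: \code{Psi_k(x) = atan2(sum_i sin(phi_ki) r_i(x),
#' sum_i cos(phi_ki) r_i(x))}, unwrapped along the track. Positions where
#' the resultant vanishes (all rates zero, or exact antipodal cancellation)
#' are flagged and carry the previous valid value.
#'
#' @param phases n_cells x 2 (or 3) matrix of per-cell phases (radians),
#'   e.g. from \code{\link{cell_spectrum}}.
#' @param rates n_cells x n_positions non-negative rate matrix.
#' @param x Track positions in cm (defaults to bin index).
#' @param source \code{"day"} or \code{"run"}.
#' @return A \code{phase_trajectory}: list with \code{x}, \code{psi1},
#'   \code{psi2}, \code{flagged}, \code{source}.
#' @export
population_phase <- function(phases, rates, x = NULL, source = "day") {
  stopifnot(is.matrix(phases), is.matrix(rates),
            nrow(phases) == nrow(rates), ncol(phases) >= 2)
  if (any(rates < 0)) stop("rates must be non-negative")
  np <- ncol(rates)
  if (is.null(x)) x <- seq_len(np)
  comp <- function(k) {
    s <- colSums(sin(phases[, k]) * rates)
    c0 <- colSums(cos(phases[, k]) * rates)
    res <- sqrt(s^2 + c0^2)
    psi <- atan2(s, c0)
    flag <- res < 1e-12
    for (i in seq_len(np)) if (flag[i]) psi[i] <- if (i > 1) psi[i - 1] else 0
    list(psi = unwrap_phase(psi), flag = flag)
  }
  c1 <- comp(1); c2 <- comp(2)
  structure(list(x = x, psi1 = c1$psi, psi2 = c2$psi,
                 flagged = c1$flag | c2$flag, source = source),
            class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("<phase_trajectory> %d positions (%s), %d flagged\n",
              length(x$x), x$source, sum(x$flagged)))
  invisible(x)
}

# Bring each component of `offset` into (-pi, pi] by subtracting multiples
# of 2*pi; returns the multiples used.
two_pi_correction <- function(offset) {
  ceiling((offset - pi) / (2 * pi))
}

#' Distance between two population phase trajectories
#'
#' The first trajectory's coordinates are corrected by multiples of 2*pi
#' per component so the start offsets lie in (-pi, pi]; both trajectories
#' are sheared onto the rhombus frame (\code{Psi1' = Psi1 + Psi2/2},
#' \code{Psi2' = sqrt(3)/2 Psi2}); the distance is the mean over track
#' positions of the Euclidean distance between same-position points.
#'
#' @param ta,tb \code{phase_trajectory} objects on the same track binning
#'   (\code{ta} is the earlier day).
#' @return Mean phase distance (radians in the sheared frame).
#' @export
trajectory_distance <- function(ta, tb) {
  stopifnot(inherits(ta, "phase_trajectory"), inherits(tb, "phase_trajectory"))
  if (length(ta$x) != length(tb$x)) stop("trajectory length mismatch")
  k1 <- two_pi_correction(ta$psi1[1] - tb$psi1[1])
  k2 <- two_pi_correction(ta$psi2[1] - tb$psi2[1])
  a <- shear_phase(ta$psi1 - 2 * pi * k1, ta$psi2 - 2 * pi * k2)
  b <- shear_phase(tb$psi1, tb$psi2)
  mean(sqrt(rowSums((a - b)^2)))
}

#' Rotation component of the trajectory difference
#'
#' Subtracts each trajectory's own starting point from all its coordinates
#' (removing lateral shift), then measures the mean sheared distance.
#'
#' @param ta,tb \code{phase_trajectory} objects on the same binning.
#' @return Mean phase distance after start alignment.
#' @export
trajectory_rotation <- function(ta, tb) {
  stopifnot(inherits(ta, "phase_trajectory"), inherits(tb, "phase_trajectory"))
  if (length(ta$x) != length(tb$x)) stop("trajectory length mismatch")
  a <- shear_phase(ta$psi1 - ta$psi1[1], ta$psi2 - ta$psi2[1])
  b <- shear_phase(tb$psi1 - tb$psi1[1], tb$psi2 - tb$psi2[1])
  mean(sqrt(rowSums((a - b)^2)))
}

#' Lateral shifts between adjacent-day trajectories, module-normalized
#'
#' The lateral shift of a day pair is the sheared, 2*pi-corrected distance
#' between the two starting points; within a module the shifts are
#' normalized by their mean across all adjacent-day pairs.
#'
#' @param pairs List of two-element lists \code{list(ta, tb)} of
#'   \code{phase_trajectory} objects (all adjacent-day pairs of one module).
#' @return Data frame: \code{pair, shift, normalized}.
#' @export
lateral_shift <- function(pairs) {
  raw <- vapply(pairs, function(p) {
    ta <- p[[1]]; tb <- p[[2]]
    k1 <- two_pi_correction(ta$psi1[1] - tb$psi1[1])
    k2 <- two_pi_correction(ta$psi2[1] - tb$psi2[1])
    a <- shear_phase(ta$psi1[1] - 2 * pi * k1, ta$psi2[1] - 2 * pi * k2)
    b <- shear_phase(tb$psi1[1], tb$psi2[1])
    sqrt(sum((a - b)^2))
  }, 1)
  data.frame(pair = seq_along(raw), shift = raw,
             normalized = raw / mean(raw))
}

#' Phase jumps along per-run trajectories and the landmark influence index
#'
#' A phase jump is the Euclidean distance between the sheared phase
#' coordinates of adjacent 1-cm positions. Jumps inside any symmetrically
#' expanded landmark zone (landmark edge plus/minus \code{expand_cm}) are
#' "within-landmark"; all others are "between-landmark". Jumps in the first
#' and last \code{edge_exclude_cm} of the track and inside the reward span
#' are discarded, as are jumps touching flagged (undefined-phase) bins.
#' The influence index of a run is its mean within-landmark jump minus the
#' run-averaged mean between-landmark jump; positive values indicate
#' landmark-driven map fragmentation.
#'
#' @param run_trajectories List of per-run \code{phase_trajectory} objects
#'   (1-cm bins).
#' @param layout A \code{track_layout}.
#' @param expand_cm Landmark expansion half-width (35 for dataset 1, 5 for
#'   simulated data).
#' @param edge_exclude_cm Track-end exclusion (default 10).
#' @param reward_span_cm Excluded reward span; defaults to the layout's
#'   reward span.
#' @return List: \code{per_run} (data frame \code{run, mean_within,
#'   mean_between, influence_index}), \code{within}, \code{between} (pooled
#'   jump values).
#' @export
phase_jumps <- function(run_trajectories, layout, expand_cm = 5,
                        edge_exclude_cm = 10, reward_span_cm = NULL) {
  if (is.null(reward_span_cm)) reward_span_cm <- layout$reward_span_cm
  edges <- layout$landmark_edges_cm
  per_run <- vector("list", length(run_trajectories))
  pooled_w <- c(); pooled_b <- c()
  for (r in seq_along(run_trajectories)) {
    tr <- run_trajectories[[r]]
    sh <- shear_phase(tr$psi1, tr$psi2)
    n <- nrow(sh)
    jump <- sqrt(rowSums((sh[-1, , drop = FALSE] - sh[-n, , drop = FALSE])^2))
    pos <- (tr$x[-1] + tr$x[-n]) / 2
    ok <- pos >= edge_exclude_cm & pos <= layout$length_cm - edge_exclude_cm
    if (!is.null(reward_span_cm))
      ok <- ok & !(pos >= reward_span_cm[1] & pos <= reward_span_cm[2])
    ok <- ok & !(tr$flagged[-1] | tr$flagged[-n])
    within <- rep(FALSE, length(pos))
    for (e in edges) within <- within | (pos >= e - expand_cm & pos <= e + expand_cm)
    w <- jump[ok & within]
    b <- jump[ok & !within]
    if (!length(b)) stop("no between-landmark bins left after exclusions")
    pooled_w <- c(pooled_w, w); pooled_b <- c(pooled_b, b)
    per_run[[r]] <- data.frame(run = r,
                               mean_within = if (length(w)) mean(w) else NA_real_,
                               mean_between = mean(b))
  }
  df <- do.call(rbind, per_run)
  df$influence_index <- df$mean_within - mean(df$mean_between, na.rm = TRUE)
  list(per_run = df, within = pooled_w, between = pooled_b)
}

#' Run-to-run correlation of a co-modular population
#'
#' For each run, computes all pairwise correlations of the cells' binned
#' activity; the run correlation of a run pair is the correlation between
#' their pairwise-correlation vectors. The shuffle control permutes cell
#' identity in the second run of each pair before recomputing.
#'
#' @param maps List of \code{run_activity_map}s (same runs; at least 6
#'   cells).
#' @param run_pairs Two-column matrix of run indices (rows of the maps);
#'   defaults to all adjacent run pairs.
#' @param n_shuffle Shuffles per pair (default 100).
#' @param seed Integer seed.
#' @return List: \code{run_corr} (data frame \code{run_a, run_b, corr}),
#'   \code{shuffle} (vector of shuffled correlations).
#' @export
run_correlation <- function(maps, run_pairs = NULL, n_shuffle = 100,
                            seed = 1) {
  stopifnot(length(maps) >= 6)
  n_runs <- nrow(maps[[1]]$values)
  if (is.null(run_pairs))
    run_pairs <- cbind(seq_len(n_runs - 1), 2:n_runs)
  acts <- lapply(seq_len(n_runs), function(r)
    t(vapply(maps, function(m) {
      v <- m$values[r, ]
      ifelse(is.na(v), 0, v)
    }, numeric(ncol(maps[[1]]$values)))))
  pair_vec <- function(act, perm = NULL) {
    if (!is.null(perm)) act <- act[perm, , drop = FALSE]
    sds <- apply(act, 1, stats::sd)
    cm <- suppressWarnings(stats::cor(t(act)))
    cm[sds == 0, ] <- NA; cm[, sds == 0] <- NA
    cm[upper.tri(cm)]
  }
  vecs <- lapply(acts, pair_vec)
  rc <- apply(run_pairs, 1, function(p)
    suppressWarnings(stats::cor(vecs[[p[1]]], vecs[[p[2]]],
                                use = "pairwise.complete.obs")))
  shuffle <- with_seed(seed, {
    unlist(lapply(seq_len(nrow(run_pairs)), function(i) {
      p <- run_pairs[i, ]
      vapply(seq_len(n_shuffle), function(s) {
        perm <- sample(length(maps))
        suppressWarnings(stats::cor(vecs[[p[1]]], pair_vec(acts[[p[2]]], perm),
                                    use = "pairwise.complete.obs"))
      }, 1)
    }))
  })
  list(run_corr = data.frame(run_a = run_pairs[, 1], run_b = run_pairs[, 2],
                             corr = rc),
       shuffle = shuffle)
}

#' Correlation between backward-field trajectories vs track distance
#'
#' For every pair of cross-day fields from different cells sharing at least
#' \code{min_overlap} runs, correlates their COM trajectories over the
#' shared runs; the pair's track distance is the absolute difference of the
#' fields' median COMs. Correlations are averaged within
#' \code{bin_cm}-wide distance bins and the Pearson trend across bins is
#' reported.
#'
#' @param fields List of \code{cross_day_field}s (with \code{cell_id} set).
#' @param bin_cm Distance bin width (default 20).
#' @param min_overlap Minimum shared runs (default 5).
#' @return List: \code{pairs} (distance, correlation per pair),
#'   \code{binned} (bin center, mean correlation, n), \code{trend}
#'   (Pearson r across bins).
#' @export
field_trajectory_correlation <- function(fields, bin_cm = 20,
                                         min_overlap = 5) {
  n <- length(fields)
  res <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (fields[[i]]$cell_id == fields[[j]]$cell_id) next
    a <- fields[[i]]$runs; b <- fields[[j]]$runs
    shared <- intersect(a$run, b$run)
    if (length(shared) < min_overlap) next
    ca <- a$com_cm[match(shared, a$run)]
    cb <- b$com_cm[match(shared, b$run)]
    if (stats::sd(ca) == 0 || stats::sd(cb) == 0) next
    res[[length(res) + 1L]] <- data.frame(
      distance_cm = abs(stats::median(a$com_cm) - stats::median(b$com_cm)),
      correlation = stats::cor(ca, cb))
  }
  if (!length(res))
    return(list(pairs = data.frame(distance_cm = numeric(0),
                                   correlation = numeric(0)),
                binned = data.frame(center_cm = numeric(0),
                                    mean_corr = numeric(0), n = integer(0)),
                trend = NA_real_))
  pairs <- do.call(rbind, res)
  bins <- floor(pairs$distance_cm / bin_cm)
  binned <- do.call(rbind, lapply(split(pairs, bins), function(d)
    data.frame(center_cm = (floor(d$distance_cm[1] / bin_cm) + 0.5) * bin_cm,
               mean_corr = mean(d$correlation), n = nrow(d))))
  binned <- binned[order(binned$center_cm), ]
  trend <- if (nrow(binned) >= 3)
    stats::cor(binned$center_cm, binned$mean_corr) else NA_real_
  list(pairs = pairs, binned = binned, trend = trend)
}
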