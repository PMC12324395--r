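# Linking internals operate on integer row indices into one run-field
# table, with per-segment statistics held in plain vectors; data frames are
# materialized only at the API boundary. This keeps the within-field
# shuffle baseline (100 relinks per cell) affordable.

# --- index-based core ------------------------------------------------------

# Stage 2 on a run-field table: returns a list of integer index vectors
# (segments), ordered by first run.
core_stage2 <- function(rf, d_run_cm) {
  n <- nrow(rf)
  if (n == 0) return(list())
  run <- rf$run; com <- rf$com_cm
  sb <- rf$start_bin; eb <- rf$end_bin; wd <- rf$width_cm
  overlap <- function(i, j) max(0, min(eb[i], eb[j]) - max(sb[i], sb[j]) + 1)
  succ <- rep(NA_integer_, n)
  dist_to <- rep(NA_real_, n)
  ov_to <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- which(run == run[i] + 1L)
    if (!length(cand)) next
    d <- abs(com[cand] - com[i])
    keep <- d <= d_run_cm
    cand <- cand[keep]; d <- d[keep]
    if (!length(cand)) next
    best <- cand[d == min(d)]
    if (length(best) > 1) {
      ov <- vapply(best, function(j) overlap(i, j), 1)
      best <- best[ov == max(ov)]
      if (length(best) > 1) {
        best <- best[wd[best] == min(wd[best])]
        if (length(best) > 1) next       # irresolvable tie: no link
      }
    }
    succ[i] <- best[1]
    dist_to[i] <- abs(com[best[1]] - com[i])
    ov_to[i] <- overlap(i, best[1])
  }
  # a successor claimed by several predecessors keeps the closest one
  # (largest overlap, then smallest width); unresolved ties keep none
  for (j in seq_len(n)) {
    preds <- which(!is.na(succ) & succ == j)
    if (length(preds) <= 1) next
    keep <- preds[dist_to[preds] == min(dist_to[preds])]
    if (length(keep) > 1) keep <- keep[ov_to[keep] == max(ov_to[keep])]
    if (length(keep) > 1) {
      keep <- keep[wd[keep] == min(wd[keep])]
      if (length(keep) > 1) keep <- integer(0)
    }
    succ[setdiff(preds, keep[1])] <- NA_integer_
    if (!length(keep)) succ[preds] <- NA_integer_
  }
  has_pred <- rep(FALSE, n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  segs <- list()
  for (i in which(!has_pred)) {
    chain <- i; k <- i
    while (!is.na(succ[k])) { k <- succ[k]; chain <- c(chain, k) }
    segs[[length(segs) + 1L]] <- chain
  }
  segs[order(vapply(segs, function(ix) min(run[ix]), 1))]
}

# Conflict resolution shared by Stages 3 and 4: among candidate indices,
# most runs, then smallest gap, then smallest track coverage; unresolved
# ties keep none.
pick_best <- function(cand, gaps, nruns, coverage) {
  keep <- cand[nruns[cand] == max(nruns[cand])]
  g <- gaps[match(keep, cand)]
  keep <- keep[g == min(g)]
  if (length(keep) > 1) {
    keep <- keep[coverage[keep] == min(coverage[keep])]
    if (length(keep) > 1) return(integer(0))
  }
  keep
}

# Stages 3 and 4 share one matching engine. `segs` is a list of index
# vectors into `rf`; `primary` is "distance" (Stage 3: closest end-to-start
# COM distance wins) or "any" (Stage 4: all accepted candidates tie and the
# most-runs/smallest-gap/smallest-coverage rule decides). "Without run
# overlap" is set-wise, so interleaved segments sharing no run are
# connectable and the run gap may be negative. Matching repeats so conflict
# losers re-choose among unclaimed partners (greedy, ascending first-run
# order) until nothing changes.
core_match <- function(rf, segs, max_gap, primary, dist_fun = NULL,
                       accept = NULL) {
  n <- length(segs)
  run <- rf$run; com <- rf$com_cm
  first <- vapply(segs, function(ix) min(run[ix]), 1)
  last <- vapply(segs, function(ix) max(run[ix]), 1)
  nruns <- lengths(segs)
  coverage <- vapply(segs, function(ix) max(com[ix]) - min(com[ix]), 1)
  run_sets <- lapply(segs, function(ix) run[ix])
  nxt <- rep(NA_integer_, n)
  barred <- matrix(FALSE, n, n)
  ord <- order(first)
  repeat {
    changed <- FALSE
    claimed <- rep(FALSE, n)
    claimed[nxt[!is.na(nxt)]] <- TRUE
    for (i in ord) {
      if (!is.na(nxt[i])) next
      cand <- which(first > first[i] & (first - last[i] - 1) <= max_gap &
                      !claimed & !barred[i, ])
      if (!length(cand)) next
      cand <- cand[vapply(cand, function(j)
        !any(run_sets[[i]] %in% run_sets[[j]]), TRUE)]
      if (!length(cand)) next
      if (primary == "distance") {
        d <- vapply(cand, function(j) dist_fun(i, j), 1)
        ok <- is.finite(d)
        cand <- cand[ok]; d <- d[ok]
        if (!length(cand)) next
        best <- cand[d == min(d)]
      } else {
        cand <- cand[vapply(cand, function(j) accept(i, j), TRUE)]
        if (!length(cand)) next
        best <- cand
      }
      if (length(best) > 1)
        best <- pick_best(best, first[best] - last[i] - 1, nruns, coverage)
      if (!length(best)) next
      nxt[i] <- best[1]
      changed <- TRUE
    }
    for (j in seq_len(n)) {
      claimants <- which(!is.na(nxt) & nxt == j)
      if (length(claimants) <= 1) next
      keep <- pick_best(claimants, first[j] - last[claimants] - 1,
                        nruns, coverage)
      drop <- if (length(keep)) setdiff(claimants, keep[1]) else claimants
      nxt[drop] <- NA_integer_
      barred[drop, j] <- TRUE
    }
    if (!changed) break
  }
  # chains -> merged index vectors (run-sorted), with member bookkeeping
  has_prev <- rep(FALSE, n)
  has_prev[nxt[!is.na(nxt)]] <- TRUE
  out <- list(); members <- list()
  for (i in which(!has_prev)) {
    chain <- i; k <- i
    while (!is.na(nxt[k])) { k <- nxt[k]; chain <- c(chain, k) }
    ix <- unlist(segs[chain])
    out[[length(out) + 1L]] <- ix[order(run[ix])]
    members[[length(members) + 1L]] <- chain
  }
  list(segments = out, members = members)
}

core_stage3 <- function(rf, segs, d_seg_cm, max_gap) {
  com <- rf$com_cm
  endcom <- vapply(segs, function(ix) mean(utils::tail(com[ix], 3)), 1)
  startcom <- vapply(segs, function(ix) mean(utils::head(com[ix], 3)), 1)
  dist_fun <- function(i, j) {
    d <- abs(startcom[j] - endcom[i])
    if (d <= d_seg_cm) d else Inf
  }
  core_match(rf, segs, max_gap, "distance", dist_fun = dist_fun)
}

core_stage4 <- function(rf, fields, d_trend_cm, max_gap) {
  run <- rf$run; com <- rf$com_cm
  lines <- lapply(fields, function(ix) {
    x <- run[ix]; y <- com[ix]
    b <- stats::cov(x, y) / stats::var(x)
    c(mean(y) - b * mean(x), b)
  })
  accept <- function(i, j) {
    li <- lines[[i]]; lj <- lines[[j]]
    e1 <- mean(abs(li[1] + li[2] * run[fields[[j]]] - com[fields[[j]]]))
    e2 <- mean(abs(lj[1] + lj[2] * run[fields[[i]]] - com[fields[[i]]]))
    e1 <= d_trend_cm && e2 <= d_trend_cm
  }
  core_match(rf, fields, max_gap, "any", accept = accept)
}

# Full Stage 2-4 pipeline on a run-field table; returns final fields as
# data frames (used both by track_fields and the shuffle baseline).
relink_fields <- function(run_fields, params) {
  segs <- core_stage2(run_fields, params$d_run_cm)
  if (!length(segs)) return(list())
  st3 <- core_stage3(run_fields, segs, params$d_seg_cm, params$max_gap_runs)
  multi <- lengths(st3$members) > 1
  assigned <- unlist(st3$members[multi])
  leftover <- setdiff(seq_along(segs), assigned)
  leftover <- leftover[lengths(segs[leftover]) > 1]
  stage4_in <- c(st3$segments[multi], segs[leftover])
  if (!length(stage4_in)) return(list())
  st4 <- core_stage4(run_fields, stage4_in, params$d_trend_cm,
                     params$max_gap_runs)
  final <- st4$segments[lengths(st4$segments) > params$min_runs]
  lapply(final, function(ix) run_fields[ix, , drop = FALSE])
}

# --- public stage-by-stage API ---------------------------------------------

#' Connect run fields in consecutive runs into cross-run segments (Stage 2)
#'
#' Each run field links to the nearest field in the next run whose COM lies
#' within \code{d_run_cm}. Distance ties are broken by largest bin overlap,
#' then smallest width, then no link. When several fields claim the same
#' successor, the predecessor with the smallest COM distance is kept, ties
#' broken by largest overlap, then smallest width, then no link. Unlinked
#' fields are retained as single-run segments for Stage 3.
#'
#' @param run_fields Data frame from \code{\link{detect_run_fields}}.
#' @param d_run_cm Stage-2 distance threshold in cm.
#' @return List of segments, each a data frame of member run fields ordered
#'   by run.
#' @export
link_adjacent_runs <- function(run_fields, d_run_cm) {
  lapply(core_stage2(run_fields, d_run_cm),
         function(ix) run_fields[ix, , drop = FALSE])
}

#' Connect cross-run segments into putative cross-day fields (Stage 3)
#'
#' An earlier-onset segment S1 connects to a later-onset segment S2 sharing
#' none of its runs when the distance between the mean COM of S1's last (up
#' to) three runs and that of S2's first three runs is minimal and within
#' \code{d_seg_cm}, and the run gap (possibly negative for interleaved
#' segments) is at most \code{max_gap}. Ties and multiple-claimant
#' conflicts resolve by most runs, smallest gap, smallest track coverage,
#' else no link; conflict losers re-choose among unclaimed partners in
#' ascending first-run order.
#'
#' @param segments List of segments from \code{\link{link_adjacent_runs}}.
#' @param d_seg_cm Stage-3 distance threshold.
#' @param max_gap Maximum number of field-free runs bridged (default 7).
#' @return List with \code{fields} (putative cross-day fields, data frames)
#'   and \code{leftover} (multi-run segments not assigned to any field).
#' @export
link_segments <- function(segments, d_seg_cm, max_gap = 7) {
  if (!length(segments)) return(list(fields = list(), leftover = list()))
  rf <- do.call(rbind, segments)
  sizes <- vapply(segments, nrow, 1L)
  idx <- split(seq_len(nrow(rf)), rep(seq_along(segments), sizes))
  st3 <- core_stage3(rf, unname(idx), d_seg_cm, max_gap)
  multi <- lengths(st3$members) > 1
  assigned <- unlist(st3$members[multi])
  leftover_idx <- setdiff(seq_along(segments), assigned)
  leftover_idx <- leftover_idx[sizes[leftover_idx] > 1]
  list(fields = lapply(st3$segments[multi],
                       function(ix) rf[ix, , drop = FALSE]),
       leftover = segments[leftover_idx])
}

#' Merge cross-day fields sharing similar COM trends (Stage 4)
#'
#' For each ordered pair F1 (earlier onset) and F2 (later onset) sharing no
#' runs and with run gap at most \code{max_gap}, a line is fit to each
#' field's COMs against run index; the fields merge when the mean absolute
#' deviation of each field's COMs from the other's extended line is within
#' \code{d_trend_cm}. Conflicts are resolved as in Stage 3. Only fields
#' with strictly more than \code{min_runs} runs are returned.
#'
#' @param fields List of candidate fields (Stage-3 output plus leftover
#'   multi-run segments), each a data frame of run fields.
#' @param d_trend_cm Stage-4 threshold in cm.
#' @param max_gap Maximum run gap (default 7).
#' @param min_runs Minimum run count (strict; default 8).
#' @return List of final cross-day fields (data frames).
#' @export
merge_by_trend <- function(fields, d_trend_cm, max_gap = 7, min_runs = 8) {
  if (!length(fields)) return(list())
  rf <- do.call(rbind, fields)
  sizes <- vapply(fields, nrow, 1L)
  idx <- split(seq_len(nrow(rf)), rep(seq_along(fields), sizes))
  st4 <- core_stage4(rf, unname(idx), d_trend_cm, max_gap)
  final <- st4$segments[lengths(st4$segments) > min_runs]
  lapply(final, function(ix) rf[ix, , drop = FALSE])
}

# OLS slope/intercept of COM on global run index.
com_line <- function(s) {
  x <- s$run; y <- s$com_cm
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}

#' Track cross-day fields of one cell (Stages 1-4)
#'
#' Runs shuffle-test detection and the three linking stages, returning the
#' final cross-day fields (strictly more than \code{params$min_runs} runs).
#'
#' @param map A \code{run_activity_map}.
#' @param params A \code{link_params}.
#' @param n_shuffles,crit,seed Passed to \code{\link{detect_run_fields}}.
#' @return List of \code{cross_day_field} objects; each has elements
#'   \code{cell_id} and \code{runs} (the member run-field table).
#' @export
track_fields <- function(map, params = link_params("simulated"),
                         n_shuffles = 1000, crit = 0.85, seed = 1) {
  rf <- detect_run_fields(map, n_shuffles, crit, params, seed)
  fields <- relink_fields(rf, params)
  lapply(fields, function(df)
    structure(list(cell_id = map$cell_id, runs = df),
              class = "cross_day_field"))
}

#' @export
print.cross_day_field <- function(x, ...) {
  cat(sprintf("<cross_day_field> %s: %d runs, days %d-%d, COM %.1f-%.1f cm\n",
              x$cell_id, nrow(x$runs), min(x$runs$day), max(x$runs$day),
              min(x$runs$com_cm), max(x$runs$com_cm)))
  invisible(x)
}

#' Normalized run-field count per run
#'
#' Counts detected run fields per run divided by covered track length: the
#' first (last) run excludes a leading (trailing) stretch of three or more
#' consecutive uncovered bins; all other runs use the full track length.
#'
#' @param map A \code{run_activity_map}.
#' @param run_fields Data frame from \code{\link{detect_run_fields}}.
#' @return Data frame with \code{run, n_fields, length_cm, count_per_cm}
#'   (NA for a fully uncovered run).
#' @export
normalized_run_field_count <- function(map, run_fields) {
  bs <- map$layout$bin_size_cm
  L <- map$layout$length_cm
  nruns <- nrow(map$values)
  out <- data.frame(run = map$run_index, n_fields = 0L,
                    length_cm = L, count_per_cm = NA_real_)
  if (nrow(run_fields))
    out$n_fields <- vapply(map$run_index,
                           function(r) sum(run_fields$run == r), 1L)
  for (i in seq_len(nruns)) {
    cov <- map$coverage_mask[i, ]
    if (!any(cov)) { out$length_cm[i] <- NA_real_; next }
    len <- L
    if (i == 1L) {
      r <- rle(cov)
      if (!r$values[1] && r$lengths[1] >= 3) len <- len - r$lengths[1] * bs
    }
    if (i == nruns) {
      r <- rle(cov)
      k <- length(r$values)
      if (!r$values[k] && r$lengths[k] >= 3) len <- len - r$lengths[k] * bs
    }
    out$length_cm[i] <- len
    out$count_per_cm[i] <- out$n_fields[i] / len
  }
  out
}
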