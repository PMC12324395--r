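#' Build a key-value memory from training runs
#'
#' Stores every (population vector, position) pair from the training block
#' as keys and values. Cells are subsampled to \code{n_cells} (120 in the
#' published setup), chosen to sample grid phases evenly by farthest-point
#' sampling on the (phi1, phi2) torus when phases are supplied; with fewer
#' cells available, all are used with a warning.
#'
#' @param train List of runs, each a list with \code{vectors} (positions x
#'   cells matrix) and \code{positions} (cm).
#' @param n_cells Subsample size (default 120).
#' @param phases Optional cells x 2 matrix of grid phases (radians) for
#'   even subsampling.
#' @param beta Softmax inverse temperature (default 1000).
#' @param radius_cm Neighborhood radius for gating (default 300).
#' @param seed Integer seed (used when phases are absent).
#' @return A \code{kv_memory}: list with \code{keys}, \code{values},
#'   \code{cells}, \code{beta}, \code{radius_cm}.
#' @export
build_memory <- function(train, n_cells = 120, phases = NULL, beta = 1000,
                         radius_cm = 300, seed = 1) {
  stopifnot(length(train) >= 1)
  total_cells <- ncol(train[[1]]$vectors)
  if (total_cells < n_cells) {
    warning(sprintf("only %d cells available; using all", total_cells))
    cells <- seq_len(total_cells)
  } else if (!is.null(phases)) {
    cells <- farthest_point_torus(phases, n_cells)
  } else {
    cells <- with_seed(seed, sort(sample(total_cells, n_cells)))
  }
  keys <- do.call(rbind, lapply(train, function(r)
    r$vectors[, cells, drop = FALSE]))
  values <- unlist(lapply(train, function(r) r$positions))
  stopifnot(nrow(keys) == length(values))
  structure(list(keys = keys, values = values, cells = cells,
                 beta = beta, radius_cm = radius_cm),
            class = "kv_memory")
}

# Farthest-point sampling on the 2D phase torus (greedy max-min under the
# wrapped Euclidean metric); deterministic: starts from the first cell.
farthest_point_torus <- function(phases, k) {
  n <- nrow(phases)
  if (k >= n) return(seq_len(n))
  tor_d2 <- function(i, j) {
    d <- abs(phases[i, ] - phases[j, ])
    d <- pmin(d, 2 * pi - d)
    sum(d^2)
  }
  chosen <- 1L
  mind <- vapply(seq_len(n), function(j) tor_d2(1L, j), 1)
  while (length(chosen) < k) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    newd <- vapply(seq_len(n), function(j) tor_d2(nxt, j), 1)
    mind <- pmin(mind, newd)
  }
  sort(chosen)
}

#' Decode position from a population vector
#'
#' Restricts the stored keys to those whose position lies within the
#' memory's neighborhood radius of the ground-truth position (eliminating
#' discontinuous predictions), scores them by cosine similarity (dot
#' product offered as an option), and applies a softmax with large inverse
#' temperature -- effectively returning the position of the most similar
#' key. Cosine is the default because an exactly stored query then recalls
#' its own position. Ties return the smallest position.
#'
#' @param query Numeric population vector (subsampled cells).
#' @param memory A \code{kv_memory}.
#' @param true_position_cm Ground-truth position for neighborhood gating.
#' @param similarity \code{"dot"} (default) or \code{"cosine"}.
#' @return Predicted position in cm.
#' @export
decode_position <- function(query, memory, true_position_cm,
                            similarity = c("cosine", "dot")) {
  similarity <- match.arg(similarity)
  ok <- abs(memory$values - true_position_cm) <= memory$radius_cm
  if (!any(ok)) stop("empty neighborhood: no keys within the gating radius")
  keys <- memory$keys[ok, , drop = FALSE]
  vals <- memory$values[ok]
  sim <- as.numeric(keys %*% query)
  if (similarity == "cosine") {
    nk <- sqrt(rowSums(keys^2)) * sqrt(sum(query^2))
    sim <- ifelse(nk > 0, sim / nk, 0)
  }
  best <- which(sim == max(sim))
  min(vals[best])
}

#' Sliding-window decoding error across learning
#'
#' Trains a key-value memory on a block of trials and evaluates the mean
#' absolute error on the following block, advancing the window by
#' \code{step} trials (model variant: train 10, test 10, step 5; the
#' real-data variant trains on 2 days and tests the next 2, evaluated
#' daily).
#'
#' @param runs List of runs, each with \code{vectors} (positions x cells)
#'   and \code{positions}.
#' @param block Training block size in trials (default 10).
#' @param eval_block Test block size (default 10).
#' @param step Evaluation stride (default 5).
#' @param n_cells,phases,beta,radius_cm,seed Passed to
#'   \code{\link{build_memory}}.
#' @param exclude_ends_cm Exclude test positions within this distance of
#'   the track ends (150 for the real-data variant; default 0).
#' @return Data frame: \code{eval_index, train_start, test_start, mae_cm}.
#' @export
sliding_window_mae <- function(runs, block = 10, eval_block = 10, step = 5,
                               n_cells = 120, phases = NULL, beta = 1000,
                               radius_cm = 300, seed = 1,
                               exclude_ends_cm = 0) {
  n <- length(runs)
  starts <- seq(1, n, by = step)
  starts <- starts[starts + block + eval_block - 1 <= n]
  if (!length(starts))
    return(data.frame(eval_index = integer(0), train_start = integer(0),
                      test_start = integer(0), mae_cm = numeric(0)))
  track_max <- max(runs[[1]]$positions)
  out <- lapply(seq_along(starts), function(i) {
    s <- starts[i]
    mem <- build_memory(runs[s:(s + block - 1)], n_cells = n_cells,
                        phases = phases, beta = beta,
                        radius_cm = radius_cm, seed = seed)
    errs <- unlist(lapply(runs[(s + block):(s + block + eval_block - 1)],
                          function(r) {
      keep <- r$positions >= exclude_ends_cm &
        r$positions <= track_max - exclude_ends_cm
      q <- r$vectors[keep, mem$cells, drop = FALSE]
      truth <- r$positions[keep]
      # cosine similarity of every key to every query, gated by neighborhood
      kn <- sqrt(rowSums(mem$keys^2)); kn[kn == 0] <- 1
      qn <- sqrt(rowSums(q^2)); qn[qn == 0] <- 1
      S <- (mem$keys / kn) %*% t(q / qn)
      preds <- vapply(seq_along(truth), function(j) {
        ok <- abs(mem$values - truth[j]) <= mem$radius_cm
        sj <- S[ok, j]
        vj <- mem$values[ok]
        min(vj[sj == max(sj)])
      }, 1)
      abs(preds - truth)
    }))
    data.frame(eval_index = i, train_start = s, test_start = s + block,
               mae_cm = mean(errs))
  })
  do.call(rbind, out)
}
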