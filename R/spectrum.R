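#' Welch power spectral density of a spatial activity trace
#'
#' Welch's averaged modified periodogram with a Hamming window of 512
#' samples, transform length 2992, overlap 461 samples (about 90%), and a
#' sampling rate of one sample per cm (the 1000 1-cm track bins). The
#' spectrum is one-sided density-scaled.
#'
#' @param x Numeric trace (day-averaged spatial activity on 1-cm bins).
#' @param window_len Window length (default 512).
#' @param nfft Transform length (default 2992).
#' @param noverlap Overlap in samples (default 461).
#' @return List: \code{freq} (cycles/cm), \code{psd}.
#' @export
pwelch_psd <- function(x, window_len = 512, nfft = 2992, noverlap = 461) {
  n <- length(x)
  stopifnot(n >= window_len)
  w <- signal::hamming(window_len)
  step <- window_len - noverlap
  starts <- seq(1, n - window_len + 1, by = step)
  u <- sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + window_len - 1)] * w
    X <- stats::fft(c(seg, rep(0, nfft - window_len)))
    P <- Mod(X[1:(nfft %/% 2 + 1)])^2 / u
    P[2:(nfft %/% 2)] <- 2 * P[2:(nfft %/% 2)]
    acc <- acc + P
  }
  list(freq = (0:(nfft %/% 2)) / nfft, psd = acc / length(starts))
}

#' Spectral peaks and phases of one grid cell
#'
#' Computes the Welch spectrum of the day-averaged 1-cm-binned activity,
#' linearly detrends it over 0.001-0.150 cycles/cm to reduce low-frequency
#' bias, and takes the three largest strict local maxima with frequency
#' above 0.006 cycles/cm. Phases are the angles of a 2992-point discrete
#' Fourier transform of the same trace at the peak frequencies. Cells with
#' fewer than three qualifying peaks are excluded from phase analysis
#' (\code{qualified = FALSE}).
#'
#' @param trace Day-averaged activity on 1-cm bins (1000 samples in the
#'   published convention).
#' @param min_freq Minimum peak frequency in cycles/cm (default 0.006).
#' @param detrend_range Frequency range for spectrum detrending.
#' @param nfft Transform length (default 2992).
#' @return List: \code{qualified}, \code{f} (sorted f1 < f2 < f3,
#'   cycles/cm), \code{power}, \code{phi} (radians), \code{freq_step}.
#' @export
cell_spectrum <- function(trace, min_freq = 0.006,
                          detrend_range = c(0.001, 0.150), nfft = 2992) {
  pw <- pwelch_psd(trace, nfft = nfft)
  sel <- pw$freq >= detrend_range[1] & pw$freq <= detrend_range[2]
  fit <- stats::lm.fit(cbind(1, pw$freq[sel]), pw$psd[sel])
  det <- pw$psd
  det[sel] <- pw$psd[sel] - cbind(1, pw$freq[sel]) %*% fit$coefficients
  search <- which(pw$freq > min_freq & pw$freq <= detrend_range[2])
  y <- det[search]
  pk <- pracma::findpeaks(y, sortstr = TRUE)
  empty <- list(qualified = FALSE, f = rep(NA_real_, 3),
                power = rep(NA_real_, 3), phi = rep(NA_real_, 3),
                freq_step = 1 / nfft)
  if (is.null(pk) || nrow(pk) < 3) return(empty)
  top <- pk[1:3, , drop = FALSE]
  idx <- search[top[, 2]]
  ord <- order(pw$freq[idx])
  idx <- idx[ord]
  X <- stats::fft(c(trace, rep(0, nfft - length(trace))))
  list(qualified = TRUE, f = pw$freq[idx], power = det[idx],
       phi = Arg(X[idx]), freq_step = 1 / nfft)
}

#' Smallest within-day field spacing of a cell
#'
#' The spacing estimate used for module assignment: the minimum distance
#' between adjacent within-day field COMs, minimized across days.
#'
#' @param day_field_tables List (one element per day) of day-level field
#'   tables as returned by \code{\link{classify_grid_cell_day}}.
#' @return Spacing in cm (NA if no day has two fields).
#' @export
cell_spacing <- function(day_field_tables) {
  sp <- vapply(day_field_tables, function(f) {
    if (is.null(f) || nrow(f) < 2) return(NA_real_)
    min(diff(sort(f$com_cm)))
  }, 1)
  if (all(!is.finite(sp))) NA_real_ else min(sp, na.rm = TRUE)
}

#' Assign cells to grid modules from their field spacings
#'
#' Pools the per-cell spacing estimates, estimates their density with a
#' Gaussian kernel, finds the density peaks and the intervening valleys,
#' and groups cells falling between two valleys into one module. A unimodal
#' density yields a single module.
#'
#' @param spacings Named numeric vector of per-cell spacings (names = cell
#'   ids).
#' @return List of modules, each a list with \code{cells},
#'   \code{spacing_range}, and \code{peak_cm}.
#' @export
assign_modules <- function(spacings) {
  spacings <- spacings[is.finite(spacings)]
  if (!length(spacings)) stop("no finite spacings")
  if (length(unique(spacings)) == 1L)
    return(list(list(cells = names(spacings),
                     spacing_range = range(spacings),
                     peak_cm = spacings[[1]])))
  d <- stats::density(spacings)
  y <- d$y
  ispeak <- which(diff(sign(diff(y))) == -2) + 1L
  ivalley <- which(diff(sign(diff(y))) == 2) + 1L
  if (!length(ispeak)) ispeak <- which.max(y)
  bounds <- c(-Inf, d$x[ivalley], Inf)
  lapply(seq_len(length(bounds) - 1L), function(k) {
    inb <- spacings >= bounds[k] & spacings < bounds[k + 1]
    pk <- d$x[ispeak][d$x[ispeak] >= bounds[k] & d$x[ispeak] < bounds[k + 1]]
    list(cells = names(spacings)[inb],
         spacing_range = if (any(inb)) range(spacings[inb]) else c(NA, NA),
         peak_cm = if (length(pk)) pk[1] else NA_real_)
  })[vapply(seq_len(length(bounds) - 1L), function(k)
    any(spacings >= bounds[k] & spacings < bounds[k + 1]), TRUE)]
}

#' Does a co-modular population qualify for phase analysis?
#'
#' Averages each cell's three peak frequencies within day, then across
#' days; the module qualifies iff it has more than 10 cells and
#' \code{|avgf1 + avgf2 - avgf3| < 0.08 * avgf3}.
#'
#' @param peaks Data frame with columns \code{cell, day, f1, f2, f3} (one
#'   row per cell and day).
#' @return List: \code{qualifying}, \code{avg_f} (length 3),
#'   \code{mismatch} (relative to avgf3), \code{n_cells}.
#' @export
qualify_module <- function(peaks) {
  stopifnot(all(c("cell", "day", "f1", "f2", "f3") %in% names(peaks)))
  per_day <- do.call(rbind, lapply(split(peaks, peaks$day), function(d)
    colMeans(d[, c("f1", "f2", "f3")], na.rm = TRUE)))
  avg <- colMeans(per_day, na.rm = TRUE)
  n_cells <- length(unique(peaks$cell))
  mismatch <- abs(avg[1] + avg[2] - avg[3]) / avg[3]
  list(qualifying = (n_cells > 10) && (mismatch < 0.08),
       avg_f = unname(avg), mismatch = unname(mismatch), n_cells = n_cells)
}
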