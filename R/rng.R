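#' Seeded randomness policy
#'
#' Every stochastic stage of the pipeline draws its seed from a master seed
#' plus a module/stage label, so a global re-run with the same master seed
#' reproduces every output exactly while different stages use decorrelated
#' streams.
#'
#' @param master_seed Integer master seed.
#' @param label Character stream label (e.g. \code{"detect"},
#'   \code{"synth/cell3"}).
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @examples
#' rng_seed(1, "detect")
#' @export
rng_seed <- function(master_seed, label = "") {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  # polynomial rolling hash over the label bytes, folded with the master
  # seed; arithmetic kept below 2^53 so doubles stay exact
  h <- 0
  for (b in utf8ToInt(paste0(label, "")))
    h <- (h * 131 + b) %% 2147483647
  as.integer((abs(master_seed) %% 2147483647 * 48271 + h) %% 2147483646)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs \code{code}, and restores the caller's RNG state.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Linear-interpolation empirical percentile (quantile type 7), the
# percentile definition used throughout the shift and reset statistics.
pctile <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE, na.rm = TRUE)
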