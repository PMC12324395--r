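#' Save run-by-run activity maps to a long-format CSV
#'
#' Writes one row per (cell, run, bin) with columns \code{cell, run, day,
#' bin, value, covered} (UTF-8, comma separator, '.' decimal, header row),
#' plus a JSON sidecar \code{<path>.layout.json} holding the track layout so
#' a round trip reproduces the maps exactly.
#'
#' @param maps A \code{run_activity_map} or list of them (shared layout).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
save_activity <- function(maps, path) {
  if (inherits(maps, "run_activity_map")) maps <- list(maps)
  stopifnot(length(maps) > 0)
  layout <- maps[[1]]$layout
  rows <- lapply(maps, function(m) {
    nb <- ncol(m$values)
    data.frame(cell = m$cell_id,
               run = rep(m$run_index, each = nb),
               day = rep(m$day_of_run, each = nb),
               bin = rep(seq_len(nb), times = nrow(m$values)),
               value = as.vector(t(m$values)),
               covered = as.vector(t(m$coverage_mask)))
  })
  df <- do.call(rbind, rows)
  df$value[!df$covered] <- 0
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  side <- list(length_cm = layout$length_cm,
               landmark_edges_cm = layout$landmark_edges_cm,
               reward_span_cm = layout$reward_span_cm,
               bin_size_cm = layout$bin_size_cm,
               landmark_width_cm = layout$landmark_width_cm,
               landmark_sides = layout$landmark_sides)
  jsonlite::write_json(side, paste0(path, ".layout.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load run-by-run activity maps from a long-format CSV
#'
#' Reads the dialect written by \code{\link{save_activity}}. Rows out of
#' (day, run) order are re-sorted with a warning; non-finite values at
#' covered bins raise a validation error naming the offending
#' (cell, run, bin) triples.
#'
#' @param path CSV path; \code{<path>.layout.json} must exist unless
#'   \code{layout} is given.
#' @param layout Optional \code{track_layout} overriding the sidecar.
#' @return Named list of \code{run_activity_map} objects.
#' @export
load_activity <- function(path, layout = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell", "run", "day", "bin", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("malformed activity CSV, missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (is.null(layout)) {
    sp <- paste0(path, ".layout.json")
    if (!file.exists(sp)) stop(sprintf("missing layout sidecar: %s", sp))
    s <- jsonlite::read_json(sp, simplifyVector = TRUE)
    layout <- track_layout(s$length_cm, s$landmark_edges_cm,
                           reward_span_cm = s$reward_span_cm,
                           bin_size_cm = s$bin_size_cm,
                           landmark_width_cm = s$landmark_width_cm,
                           landmark_sides = s$landmark_sides)
  }
  if (!"covered" %in% names(df)) df$covered <- TRUE
  bad <- df$covered & !is.finite(df$value)
  if (any(bad)) {
    w <- utils::head(which(bad), 5)
    stop(sprintf("non-finite values at: %s",
                 paste(sprintf("(%s, run %d, bin %d)", df$cell[w],
                               df$run[w], df$bin[w]), collapse = ", ")))
  }
  maps <- lapply(split(df, df$cell), function(d) {
    runs <- unique(d[order(d$day, d$run), c("run", "day")])
    nb <- layout$n_bins
    vals <- matrix(NA_real_, nrow(runs), nb)
    cov <- matrix(FALSE, nrow(runs), nb)
    ridx <- match(d$run, runs$run)
    vals[cbind(ridx, d$bin)] <- d$value
    cov[cbind(ridx, d$bin)] <- d$covered
    vals[!cov] <- NA_real_
    run_activity_map(vals, runs$day, layout, cell_id = d$cell[1],
                     run_index = runs$run, coverage_mask = cov)
  })
  maps[order(names(maps))]
}

# Polynomial rolling hash of a character string, hex-encoded (config
# fingerprinting; arithmetic below 2^53 so doubles stay exact).
fnv1a_hex <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s))
    h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Hash a configuration object
#'
#' Deterministic hex fingerprint of any JSON-serialisable configuration;
#' recorded in result sidecars so outputs can be traced to the exact
#' settings that produced them.
#' @param config A list (or any JSON-serialisable object).
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  fnv1a_hex(as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)))
}

#' Save flat result tables with a provenance sidecar
#'
#' Writes each named table as \code{<stem>_<name>.csv} and a single JSON
#' sidecar \code{<stem>.meta.json} recording the config hash, seed and
#' package version. Empty tables produce header-only CSVs.
#'
#' @param tables Named list of data frames.
#' @param stem Output path stem (without extension).
#' @param config Configuration list used to produce the tables.
#' @param seed Master seed used.
#' @return Character vector of files written, invisibly.
#' @export
save_results <- function(tables, stem, config = list(), seed = NA_integer_) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  files <- character(0)
  for (nm in names(tables)) {
    f <- sprintf("%s_%s.csv", stem, nm)
    utils::write.csv(tables[[nm]], f, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    files <- c(files, f)
  }
  meta <- list(config_hash = config_hash(config), seed = seed,
               package_version = as.character(utils::packageVersion("gridshift")))
  mf <- sprintf("%s.meta.json", stem)
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}
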