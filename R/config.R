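#' Study configuration
#'
#' Collects the constants that parameterize every stage of the pipeline:
#' the night window used for home inference, the number of ranked home
#' cells, the k-anonymity threshold applied to every published aggregate,
#' the Earth radius used for great-circle distances, the collocation
#' bucket width, the baseline window for trend normalization and the
#' moving-average window.
#'
#' @param night_start Clock time `"HH:MM"` opening the night window
#'   (default `"22:00"`).
#' @param night_end Clock time `"HH:MM"` closing the night window
#'   (default `"05:00"`). A start later than the end means the window
#'   spans midnight, and events before `night_end` are attributed to the
#'   previous calendar date's night.
#' @param n_home_cells Number of ranked night cells retained per
#'   subscriber-night (default 3).
#' @param k_anonymity Minimum number of distinct contributing subscribers
#'   for an aggregate to be published (default 50); aggregates below the
#'   threshold are suppressed and exported as missing.
#' @param earth_radius_km Sphere radius in km for haversine distances
#'   (default 6371.0, the conventional mean Earth radius).
#' @param collocation_bucket_minutes Width of the collocation time
#'   buckets in minutes; must divide 1440 (default 60).
#' @param baseline_window Length-2 vector of dates (coercible with
#'   [as.Date()]) bounding the baseline period, inclusive. `NULL`
#'   (default) means the first `moving_average_days` calendar days of the
#'   series, which reproduces a "first week" pre-pandemic baseline when
#'   the series starts at the reference week.
#' @param moving_average_days Trailing moving-average window in days
#'   (default 7).
#' @param dwell_mode How "time seen" in a cell is allocated from point
#'   events: `"midpoint"` (default) splits each inter-event gap at its
#'   midpoint between the two bounding cells; `"counts"` uses the event
#'   count ratio instead, as a sensitivity check.
#' @param od_count_mode `"persons"` (default) counts each ordered region
#'   pair at most once per subscriber per day; `"trips"` tallies every
#'   collapsed transition.
#' @param study_window Optional length-2 vector of dates; events outside
#'   it are dropped (with a count) at read time. `NULL` keeps everything.
#'
#' @return An object of class `study_config` (a named list).
#' @export
#' @examples
#' cfg <- study_config(k_anonymity = 20)
#' cfg$night_start_min / 60  # night opens at 22h
study_config <- function(night_start = "22:00",
                         night_end = "05:00",
                         n_home_cells = 3L,
                         k_anonymity = 50L,
                         earth_radius_km = 6371.0,
                         collocation_bucket_minutes = 60L,
                         baseline_window = NULL,
                         moving_average_days = 7L,
                         dwell_mode = c("midpoint", "counts"),
                         od_count_mode = c("persons", "trips"),
                         study_window = NULL) {
  dwell_mode <- match.arg(dwell_mode)
  od_count_mode <- match.arg(od_count_mode)
  n_home_cells <- as.integer(n_home_cells)
  k_anonymity <- as.integer(k_anonymity)
  collocation_bucket_minutes <- as.integer(collocation_bucket_minutes)
  moving_average_days <- as.integer(moving_average_days)

  if (is.na(k_anonymity) || k_anonymity < 1L) {
    stop("k_anonymity must be >= 1", call. = FALSE)
  }
  if (is.na(n_home_cells) || n_home_cells < 1L) {
    stop("n_home_cells must be >= 1", call. = FALSE)
  }
  if (is.na(collocation_bucket_minutes) ||
      collocation_bucket_minutes < 1L ||
      1440L %% collocation_bucket_minutes != 0L) {
    stop("collocation_bucket_minutes must divide 1440", call. = FALSE)
  }
  if (moving_average_days < 1L) {
    stop("moving_average_days must be >= 1", call. = FALSE)
  }
  if (!is.numeric(earth_radius_km) || earth_radius_km <= 0) {
    stop("earth_radius_km must be positive", call. = FALSE)
  }
  if (!is.null(baseline_window)) {
    baseline_window <- as.Date(baseline_window)
    if (length(baseline_window) != 2L || anyNA(baseline_window) ||
        baseline_window[1] > baseline_window[2]) {
      stop("baseline_window must be two ordered dates", call. = FALSE)
    }
  }
  if (!is.null(study_window)) {
    study_window <- as.Date(study_window)
    if (length(study_window) != 2L || anyNA(study_window) ||
        study_window[1] > study_window[2]) {
      stop("study_window must be two ordered dates", call. = FALSE)
    }
  }

  cfg <- list(
    night_start = night_start,
    night_end = night_end,
    night_start_min = parse_clock_minutes(night_start),
    night_end_min = parse_clock_minutes(night_end),
    n_home_cells = n_home_cells,
    k_anonymity = k_anonymity,
    earth_radius_km = as.numeric(earth_radius_km),
    collocation_bucket_minutes = collocation_bucket_minutes,
    baseline_window = baseline_window,
    moving_average_days = moving_average_days,
    dwell_mode = dwell_mode,
    od_count_mode = od_count_mode,
    study_window = study_window
  )
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  night window      :", x$night_start, "-", x$night_end, "\n")
  cat("  ranked home cells :", x$n_home_cells, "\n")
  cat("  k-anonymity       :", x$k_anonymity, "\n")
  cat("  earth radius (km) :", x$earth_radius_km, "\n")
  cat("  collocation bucket:", x$collocation_bucket_minutes, "min\n")
  cat("  moving average    :", x$moving_average_days, "days\n")
  cat("  dwell mode        :", x$dwell_mode, "\n")
  invisible(x)
}

#' Read a study configuration from a YAML file
#'
#' The file may contain any subset of the [study_config()] arguments;
#' unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(study_config, raw)
}

# Serialize a config to a stable JSON string (manifest fingerprinting)
config_as_json <- function(config) {
  x <- unclass(config)
  x$baseline_window <- if (is.null(x$baseline_window)) NULL else as.character(x$baseline_window)
  x$study_window <- if (is.null(x$study_window)) NULL else as.character(x$study_window)
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
}
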