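#' Read a pseudonymous event table
#'
#' Reads a CSV of network sightings with columns `subscriber_id`,
#' `timestamp` (ISO-8601 `YYYY-MM-DDTHH:MM:SS`, local civil time) and
#' `cell_id`. Rows with unparseable timestamps or empty identifiers are
#' dropped and counted via a message; events outside a configured study
#' window are likewise dropped. Whether the referenced cells exist is not
#' checked here — that is [validate_dataset()]'s job.
#'
#' @param path Path to the events CSV.
#' @param config A [study_config()]; only its `study_window` is consulted.
#' @return A `data.table` with columns `subscriber_id` (character),
#'   `timestamp` (POSIXct, civil clock stored as UTC) and `cell_id`
#'   (character), sorted by `(timestamp, subscriber_id, cell_id)` so that
#'   the order is total and deterministic.
#' @export
read_events <- function(path, config = study_config()) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = "character", showProgress = FALSE)
  required <- c("subscriber_id", "timestamp", "cell_id")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("events file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dt <- dt[, required, with = FALSE]
  n_in <- nrow(dt)
  dt[, timestamp := parse_timestamp(timestamp)]
  bad <- is.na(dt$timestamp) | !nzchar(dt$subscriber_id) | !nzchar(dt$cell_id)
  n_bad <- sum(bad)
  if (n_bad > 0L) {
    message("read_events: rejected ", n_bad, " malformed row(s) of ", n_in)
    dt <- dt[!bad]
  }
  if (!is.null(config$study_window)) {
    d <- as.Date(ts_date(dt$timestamp))
    outside <- d < config$study_window[1] | d > config$study_window[2]
    if (any(outside)) {
      message("read_events: dropped ", sum(outside), " row(s) outside study window")
      dt <- dt[!outside]
    }
  }
  if (nrow(dt) == 0L) stop("no parseable event rows in ", path, call. = FALSE)
  data.table::setorder(dt, timestamp, subscriber_id, cell_id)
  dt[]
}

#' Read a cell-site registry
#'
#' CSV with columns `cell_id`, `lat`, `lon`, `region_id`. Duplicate cell
#' ids and out-of-range coordinates are fatal, naming the offending cell.
#'
#' @param path Path to the registry CSV.
#' @return A `data.table` keyed by `cell_id`.
#' @export
read_cell_registry <- function(path) {
  if (!file.exists(path)) stop("cell registry not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, showProgress = FALSE)
  required <- c("cell_id", "lat", "lon", "region_id")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("cell registry missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dt <- dt[, required, with = FALSE]
  dt[, cell_id := as.character(cell_id)]
  dt[, region_id := as.character(region_id)]
  dup <- dt$cell_id[duplicated(dt$cell_id)]
  if (length(dup)) {
    stop("duplicate cell_id in registry: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- is.na(dt$lat) | is.na(dt$lon) |
    dt$lat < -90 | dt$lat > 90 | dt$lon < -180 | dt$lon > 180
  if (any(bad)) {
    stop("out-of-range coordinates for cell_id: ",
         paste(dt$cell_id[bad], collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(dt$region_id) | is.na(dt$region_id))) {
    stop("empty region_id in registry", call. = FALSE)
  }
  data.table::setkey(dt, cell_id)
  dt[]
}

#' Read a region population table
#'
#' CSV with columns `region_id`, `population`. Populations must be
#' positive; duplicate regions are fatal.
#'
#' @param path Path to the population CSV.
#' @return A `data.table` keyed by `region_id`.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("population file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, showProgress = FALSE)
  required <- c("region_id", "population")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("population file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dt <- dt[, required, with = FALSE]
  dt[, region_id := as.character(region_id)]
  dup <- dt$region_id[duplicated(dt$region_id)]
  if (length(dup)) {
    stop("duplicate region_id in population table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(dt$population) | dt$population <= 0)) {
    stop("population must be a positive count for every region", call. = FALSE)
  }
  data.table::setkey(dt, region_id)
  dt[]
}

#' Cross-validate events, registry and population tables
#'
#' Produces a report of referential problems: events pointing at cells
#' absent from the registry, and registry regions absent from the
#' population table. The report never throws; callers decide whether to
#' stop (the pipeline refuses to proceed on unknown-cell events unless
#' told to drop them).
#'
#' @param events Event table from [read_events()].
#' @param registry Registry from [read_cell_registry()].
#' @param population Population table from [read_population()].
#' @return A list of class `mobikit_validation` with elements
#'   `n_events`, `n_unknown_cell_events`, `unknown_cells`,
#'   `missing_population_regions` and `ok`.
#' @export
validate_dataset <- function(events, registry, population) {
  unknown <- !(events$cell_id %in% registry$cell_id)
  missing_regions <- setdiff(registry$region_id, population$region_id)
  out <- list(
    n_events = nrow(events),
    n_unknown_cell_events = sum(unknown),
    unknown_cells = sort(unique(events$cell_id[unknown])),
    missing_population_regions = sort(missing_regions),
    ok = !any(unknown) && length(missing_regions) == 0L
  )
  class(out) <- "mobikit_validation"
  out
}

#' @export
print.mobikit_validation <- function(x, ...) {
  cat("<mobikit_validation> ", if (x$ok) "OK" else "PROBLEMS", "\n", sep = "")
  cat("  events                 :", x$n_events, "\n")
  cat("  unknown-cell events    :", x$n_unknown_cell_events, "\n")
  if (length(x$unknown_cells)) {
    cat("  unknown cells          :", paste(head(x$unknown_cells, 10), collapse = ", "), "\n")
  }
  if (length(x$missing_population_regions)) {
    cat("  regions w/o population :",
        paste(x$missing_population_regions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an event table in the canonical CSV layout
#'
#' @param events Event table (`subscriber_id`, `timestamp`, `cell_id`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.table::data.table(
    subscriber_id = events$subscriber_id,
    timestamp = format_timestamp(events$timestamp),
    cell_id = events$cell_id
  )
  write_output_csv(out, path)
}
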