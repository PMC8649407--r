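library(data.table)

# Build an event table from parallel vectors; timestamps as
# "YYYY-MM-DD HH:MM[:SS]" strings.
make_events <- function(subscriber_id, timestamp, cell_id) {
  dt <- data.table(
    subscriber_id = subscriber_id,
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    cell_id = cell_id
  )
  setorder(dt, timestamp, subscriber_id, cell_id)
  dt[]
}

# A small two-region registry with hand-placed coordinates.
toy_registry <- function() {
  data.table(
    cell_id = c("A", "B", "C", "D", "E"),
    lat = c(40.00, 40.03, 40.06, 41.00, 41.02),
    lon = c(0.00, 0.02, 0.05, 0.00, 0.03),
    region_id = c("R1", "R1", "R1", "R2", "R2")
  )
}

toy_population <- function() {
  data.table(region_id = c("R1", "R2"), population = c(1000L, 500L))
}

# A registry where distances from a "home" cell are controlled: cells on
# the equator-ish meridian at given km offsets north of home.
registry_at_km <- function(home = "H", offsets_km, ids = NULL,
                           radius_km = 6371) {
  ids <- ids %||% paste0("K", seq_along(offsets_km))
  deg <- offsets_km / (radius_km * pi / 180)
  data.table(
    cell_id = c(home, ids),
    lat = c(0, deg),
    lon = 0,
    region_id = "R1"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random event fixture over a registry: n events, n_sub subscribers, one
# calendar day, minute-resolution times.
random_day_events <- function(registry, n = 200, n_sub = 5, seed = 1,
                              date = "2020-03-01") {
  set.seed(seed)
  make_events(
    subscriber_id = sprintf("s%02d", sample.int(n_sub, n, replace = TRUE)),
    timestamp = paste0(date, " ",
                       sprintf("%02d:%02d:00",
                               sample(0:23, n, replace = TRUE),
                               sample(0:59, n, replace = TRUE))),
    cell_id = sample(registry$cell_id, n, replace = TRUE)
  )
}

small_scenario <- function(...) {
  defaults <- list(
    n_regions = 2L, cells_per_region = 10L, n_subscribers = 60L,
    start_date = "2020-02-01", end_date = "2020-02-10",
    lockdown_date = "2020-02-06", mobility_reduction = 0.3,
    events_per_day_mean = 10, rng_seed = 99L
  )
  args <- utils::modifyList(defaults, list(...), keep.null = TRUE)
  do.call(sim_scenario, args)
}
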