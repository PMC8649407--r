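#' Dwell time per cell from point events
#'
#' Network sightings are instants, not intervals, so "time seen" in a
#' cell has to be allocated. In the default `"midpoint"` mode each gap
#' between consecutive events is split at its midpoint between the two
#' bounding events' cells; the first and last events of a day absorb time
#' only inward, so no time is extrapolated beyond the observed span and
#' per-cell dwell always sums exactly to `t_total`, the first-to-last
#' span. In `"counts"` mode dwell is proportional to event counts (a
#' sensitivity check). A single-event day has `t_total = 0` and is
#' flagged degenerate.
#'
#' @param events Sorted event table (any number of subscribers and days).
#' @param config A [study_config()]; `dwell_mode` selects the allocation.
#' @return A list with `dwell` (per subscriber-date-cell `dwell_seconds`)
#'   and `totals` (per subscriber-date `t_total_s`, `n_events`,
#'   `degenerate`).
#' @export
dwell_times <- function(events, config = study_config()) {
  ev <- data.table::copy(events)
  ev[, date := ts_date(timestamp)]
  data.table::setorder(ev, subscriber_id, date, timestamp, cell_id)

  if (config$dwell_mode == "midpoint") {
    ev[, w := {
      s <- as.numeric(timestamp)
      g <- diff(s)
      (c(0, g) + c(g, 0)) / 2
    }, by = .(subscriber_id, date)]
  } else {  # counts mode: equal share of the span per event
    ev[, w := {
      s <- as.numeric(timestamp)
      rep((s[.N] - s[1]) / .N, .N)
    }, by = .(subscriber_id, date)]
  }

  dwell <- ev[, .(dwell_seconds = sum(w)), by = .(subscriber_id, date, cell_id)]
  totals <- ev[, .(
    t_total_s = as.numeric(timestamp[.N]) - as.numeric(timestamp[1]),
    n_events = .N
  ), by = .(subscriber_id, date)]
  totals[, degenerate := t_total_s <= 0]
  list(dwell = dwell[], totals = totals[])
}

#' Percent of observed time spent at the home cells
#'
#' The ratio of the time a subscriber is seen at any of their ranked home
#' cells of that date to the total time they are seen in the network that
#' day. Subscriber-days with no home assignment are missing, not zero.
#' Degenerate days (a single sighting, `t_total = 0`) are 1 when the
#' sighting is at a home cell and 0 otherwise.
#'
#' @param dwell The list returned by [dwell_times()].
#' @param homes Home table from [infer_homes()].
#' @return Per subscriber-date `data.table` with `pct_time_home` in
#'   \[0, 1\] (NA when no home is known).
#' @export
pct_time_home <- function(dwell, homes) {
  hs <- home_cell_sets(homes)
  home_dwell <- dwell$dwell[hs, on = .(subscriber_id, date, cell_id), nomatch = NULL]
  agg <- home_dwell[, .(t_home = sum(dwell_seconds), n_home_cells_seen = .N),
                    by = .(subscriber_id, date)]

  has_home <- unique(hs[, .(subscriber_id, date)])
  has_home[, has_home := TRUE]

  out <- merge(dwell$totals, agg, by = c("subscriber_id", "date"), all.x = TRUE)
  out <- merge(out, has_home, by = c("subscriber_id", "date"), all.x = TRUE)
  out[is.na(has_home), has_home := FALSE]
  out[is.na(t_home), t_home := 0]
  out[is.na(n_home_cells_seen), n_home_cells_seen := 0L]

  # degenerate day (t_total = 0): home membership of the sighting(s) decides
  out[, pct_time_home := ifelse(
    !has_home, NA_real_,
    ifelse(degenerate, as.numeric(n_home_cells_seen > 0L), t_home / t_total_s)
  )]
  out[, .(subscriber_id, date, pct_time_home)]
}

#' Daily radius of gyration about the top home cell
#'
#' Root-mean-square great-circle distance between the *distinct* cells a
#' subscriber visited that day and their rank-1 home cell — each visited
#' cell counts once, independently of how many events it served. Missing
#' home assignments yield a missing indicator.
#'
#' @param events Sorted event table.
#' @param homes Home table from [infer_homes()].
#' @param registry Cell registry.
#' @param config A [study_config()]; supplies `earth_radius_km`.
#' @return Per subscriber-date `data.table` with `rog_km`.
#' @export
radius_of_gyration <- function(events, homes, registry, config = study_config()) {
  ev <- unique(data.table::data.table(
    subscriber_id = events$subscriber_id,
    date = ts_date(events$timestamp),
    cell_id = events$cell_id
  ))
  th <- top_homes(homes)
  ev <- th[ev, on = .(subscriber_id, date)]
  ev <- registry[, .(cell_id, lat, lon)][ev, on = "cell_id"]
  ev <- registry[, .(home_cell = cell_id, home_lat = lat, home_lon = lon)][
    ev, on = "home_cell"]
  ev[, d_km := NA_real_]
  ev[!is.na(home_cell), d_km := haversine_km(lat, lon, home_lat, home_lon,
                                             config$earth_radius_km)]
  out <- ev[, .(rog_km = if (anyNA(d_km)) NA_real_ else sqrt(mean(d_km^2))),
            by = .(subscriber_id, date)]
  out[]
}

#' Distinct cells visited per subscriber-day
#'
#' @param events Sorted event table.
#' @return Per subscriber-date `data.table` with `n_cells_visited`.
#' @export
distinct_cells_visited <- function(events) {
  ev <- data.table::data.table(
    subscriber_id = events$subscriber_id,
    date = ts_date(events$timestamp),
    cell_id = events$cell_id
  )
  ev[, .(n_cells_visited = data.table::uniqueN(cell_id)),
     by = .(subscriber_id, date)]
}

#' Collocation: cohort sizes in non-home cell/time buckets
#'
#' The day is cut into fixed clock-aligned buckets (default 60 minutes,
#' `[00:00, 01:00)`, ...). For every (cell, bucket) the cohort is the
#' number of distinct subscribers seen there whose ranked home cells do
#' *not* include that cell — people at their own home cell are assumed to
#' be at home and are excluded. A subscriber's daily exposure is the mean
#' cohort size over their qualifying (cell, bucket) sightings; with no
#' qualifying sighting the exposure is missing. Subscribers without a
#' home assignment have an empty home set, so all their sightings
#' qualify.
#'
#' @param events Sorted event table (typically a full day or more).
#' @param homes Home table from [infer_homes()].
#' @param config A [study_config()].
#' @return A list with `exposure` (per subscriber-date
#'   `collocation_exposure`) and `cohorts` (per date-cell-bucket cohort
#'   size, the count of qualifying distinct subscribers).
#' @export
collocation <- function(events, homes, config = study_config()) {
  bw <- config$collocation_bucket_minutes
  pres <- unique(data.table::data.table(
    subscriber_id = events$subscriber_id,
    date = ts_date(events$timestamp),
    bucket = ts_minute(events$timestamp) %/% bw,
    cell_id = events$cell_id
  ))
  hs <- home_cell_sets(homes)
  hs[, qualifies := FALSE]
  pres <- hs[pres, on = .(subscriber_id, date, cell_id)]
  pres[is.na(qualifies), qualifies := TRUE]   # not a home cell of that day
  pres <- pres[qualifies == TRUE]

  cohorts <- pres[, .(cohort = data.table::uniqueN(subscriber_id)),
                  by = .(date, cell_id, bucket)]
  exposure <- cohorts[pres, on = .(date, cell_id, bucket)][
    , .(collocation_exposure = mean(cohort)), by = .(subscriber_id, date)]
  list(exposure = exposure[], cohorts = cohorts[])
}

#' Compute all four daily behavioral indicators
#'
#' Joins percent time at home, radius of gyration, distinct cells visited
#' and collocation exposure into one row per subscriber-day. Indicators
#' whose prerequisites are absent (e.g. no home assignment that night)
#' are NA.
#'
#' @param events Sorted event table.
#' @param homes Home table from [infer_homes()].
#' @param registry Cell registry.
#' @param config A [study_config()].
#' @return Per subscriber-date `data.table` with columns
#'   `pct_time_home`, `rog_km`, `n_cells_visited`,
#'   `collocation_exposure`.
#' @export
compute_daily_kpis <- function(events, homes, registry, config = study_config()) {
  dw <- dwell_times(events, config)
  pth <- pct_time_home(dw, homes)
  rog <- radius_of_gyration(events, homes, registry, config)
  ncv <- distinct_cells_visited(events)
  col <- collocation(events, homes, config)$exposure

  out <- Reduce(function(a, b) merge(a, b, by = c("subscriber_id", "date"), all = TRUE),
                list(pth, rog, ncv, col))
  data.table::setorder(out, subscriber_id, date)
  out[]
}
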