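#' Region transitions of one subscriber-day
#'
#' Maps each event to its region, collapses consecutive same-region runs
#' and reads off every adjacent pair of distinct regions. In `"persons"`
#' mode the result is the *set* of distinct ordered pairs — a person
#' moving A to B twice in one day still counts once, because the matrix
#' estimates the number of *people* moving. `"trips"` mode keeps every
#' collapsed transition with its multiplicity.
#'
#' @param events Time-sorted events of a single subscriber and day.
#' @param registry Cell registry (for the cell-to-region map).
#' @param config A [study_config()]; `od_count_mode` selects the mode.
#' @return A `data.table` with `origin_region`, `destination_region` and
#'   `n` (1 for every row in `"persons"` mode).
#' @export
extract_transitions <- function(events, registry, config = study_config()) {
  regions <- registry$region_id[match(events$cell_id, registry$cell_id)]
  if (anyNA(regions)) {
    stop("events reference cells missing from the registry", call. = FALSE)
  }
  collapsed <- rle(regions)$values
  if (length(collapsed) < 2L) {
    return(data.table::data.table(origin_region = character(0),
                                  destination_region = character(0),
                                  n = integer(0)))
  }
  pairs <- data.table::data.table(
    origin_region = collapsed[-length(collapsed)],
    destination_region = collapsed[-1L]
  )
  if (config$od_count_mode == "persons") {
    pairs <- unique(pairs)
    pairs[, n := 1L]
  } else {
    pairs <- pairs[, .(n = .N), by = .(origin_region, destination_region)]
  }
  pairs[]
}

#' Daily origin-destination matrices from an event table
#'
#' Applies [extract_transitions()] per subscriber-day (vectorized) and
#' tallies, per date and ordered region pair, the raw movement count and
#' the number of distinct contributing subscribers. In the default
#' `"persons"` mode the two coincide. Stationary subscribers contribute
#' nothing; the diagonal is never emitted.
#'
#' @param events Sorted event table.
#' @param registry Cell registry.
#' @param config A [study_config()].
#' @return A `data.table` with `date`, `origin_region`,
#'   `destination_region`, `raw_count`, `contributing_subscribers`.
#' @export
build_od_matrix <- function(events, registry, config = study_config()) {
  ev <- data.table::data.table(
    subscriber_id = events$subscriber_id,
    timestamp = events$timestamp,
    date = ts_date(events$timestamp),
    region_id = registry$region_id[match(events$cell_id, registry$cell_id)]
  )
  if (anyNA(ev$region_id)) {
    stop("events reference cells missing from the registry", call. = FALSE)
  }
  data.table::setorder(ev, subscriber_id, date, timestamp)
  # collapse consecutive same-region runs within each subscriber-day
  ev[, keep := region_id != data.table::shift(region_id, fill = "\x01"),
     by = .(subscriber_id, date)]
  seqs <- ev[keep == TRUE]
  seqs[, pair_id := seq_len(.N)]
  trans <- seqs[, .(
    origin_region = region_id[-.N],
    destination_region = region_id[-1L]
  ), by = .(subscriber_id, date)]
  if (nrow(trans) == 0L) {
    return(data.table::data.table(
      date = as.IDate(integer(0)), origin_region = character(0),
      destination_region = character(0), raw_count = integer(0),
      contributing_subscribers = integer(0)
    ))
  }
  if (config$od_count_mode == "persons") {
    trans <- unique(trans)
  }
  od <- trans[, .(
    raw_count = .N,
    contributing_subscribers = data.table::uniqueN(subscriber_id)
  ), by = .(date, origin_region, destination_region)]
  data.table::setorder(od, date, origin_region, destination_region)
  od[]
}

#' Population scaling multipliers from previous-night homes
#'
#' For each region and date, counts the subscribers whose rank-1 home
#' cell of the *previous* night lies in the region, and divides the
#' region's census population by that count. Multiplying a subscriber
#' count by the multiplier extrapolates it to a population-level person
#' count. Regions with zero resident subscribers on a night get a
#' missing multiplier (with a warning).
#'
#' @param homes Home table from [infer_homes()].
#' @param registry Cell registry.
#' @param population Region population table.
#' @return A `data.table` with `date` (the day the multiplier applies
#'   to, i.e. the night date + 1), `region_id`, `customers_home`,
#'   `multiplier`.
#' @export
compute_scaling <- function(homes, registry, population) {
  missing_regions <- setdiff(registry$region_id, population$region_id)
  if (length(missing_regions)) {
    stop("regions missing from population table: ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  }
  th <- top_homes(homes)
  th[, region_id := registry$region_id[match(home_cell, registry$cell_id)]]
  counts <- th[, .(customers_home = data.table::uniqueN(subscriber_id)),
               by = .(date, region_id)]
  # every region appears for every night, even with zero residents
  grid <- data.table::CJ(date = unique(counts$date),
                         region_id = population$region_id)
  counts <- counts[grid, on = .(date, region_id)]
  counts[is.na(customers_home), customers_home := 0L]
  counts <- population[counts, on = "region_id"]
  counts[, multiplier := ifelse(customers_home > 0L,
                                population / customers_home, NA_real_)]
  if (anyNA(counts$multiplier)) {
    warning("regions with zero home subscribers on some nights; ",
            "their multipliers are missing", call. = FALSE)
  }
  # the previous night's homes scale the following day's flows
  counts[, date := date + 1L]
  out <- counts[, .(date, region_id, customers_home, multiplier)]
  data.table::setorder(out, date, region_id)
  out[]
}

#' Scale an origin-destination matrix to population level
#'
#' Each flow is multiplied by its *origin* region's multiplier for that
#' date, anchoring the extrapolation to where the movers were resident
#' the previous night. Missing multipliers propagate to missing scaled
#' counts.
#'
#' @param od Raw matrix from [build_od_matrix()].
#' @param scaling Multipliers from [compute_scaling()].
#' @return The matrix with a `scaled_count` column.
#' @export
scale_od_matrix <- function(od, scaling) {
  mult <- scaling[, .(date, origin_region = region_id, multiplier)]
  out <- mult[od, on = .(date, origin_region)]
  out[, scaled_count := raw_count * multiplier]
  out[, multiplier := NULL]
  data.table::setcolorder(out, c("date", "origin_region", "destination_region",
                                 "raw_count", "contributing_subscribers",
                                 "scaled_count"))
  data.table::setorder(out, date, origin_region, destination_region)
  out[]
}
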