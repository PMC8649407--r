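#' Restrict events to the night window and label each with its night
#'
#' Keeps events whose clock time lies in the configured night window
#' (default 22:00-05:00). Because the window spans midnight, events
#' before the window's end (e.g. 04:59) belong to the *previous* calendar
#' date's night: a night is one sleep period, anchored to the evening it
#' starts on.
#'
#' @param events Sorted event table.
#' @param config A [study_config()].
#' @return The night events with an extra `night_date` column (`IDate`).
#' @export
#' @examples
#' ev <- data.table::data.table(
#'   subscriber_id = "a",
#'   timestamp = as.POSIXct(c("2020-02-01 23:30:00", "2020-02-02 04:59:00",
#'                            "2020-02-02 12:00:00"), tz = "UTC"),
#'   cell_id = "C1"
#' )
#' night_filter(ev, study_config())$night_date  # both nights are Feb 1
night_filter <- function(events, config = study_config()) {
  ns <- config$night_start_min
  ne <- config$night_end_min
  m <- ts_minute(events$timestamp)
  d <- ts_date(events$timestamp)
  if (ns > ne) {            # window spans midnight
    keep <- m >= ns | m < ne
    nd <- d - (m < ne)
  } else {                  # degenerate: window within one day
    keep <- m >= ns & m < ne
    nd <- d
  }
  out <- events[keep]
  out[, night_date := nd[keep]]
  out[]
}

#' Rank the night cells of one subscriber-night
#'
#' Counts night events per cell and returns the `n_home_cells` most
#' frequent cells in descending count order; ties are broken by
#' lexicographically ascending `cell_id` so the ranking is deterministic.
#' An empty input yields an empty ranking with a zero event count.
#'
#' @param events Night events of a single subscriber-night (only
#'   `cell_id` is consulted).
#' @param config A [study_config()].
#' @return A list of class `home_assignment` with `ranked_home_cells`
#'   (character vector, possibly empty) and `night_event_count`.
#' @export
infer_home_cells <- function(events, config = study_config()) {
  cells <- if (is.data.frame(events)) events$cell_id else as.character(events)
  if (length(cells) == 0L) {
    out <- list(ranked_home_cells = character(0), night_event_count = 0L)
  } else {
    counts <- table(cells)
    ord <- order(-as.integer(counts), names(counts))
    out <- list(
      ranked_home_cells = names(counts)[ord][seq_len(min(config$n_home_cells, length(counts)))],
      night_event_count = length(cells)
    )
  }
  class(out) <- "home_assignment"
  out
}

#' Most likely home cell of an assignment
#'
#' @param assignment A `home_assignment` from [infer_home_cells()], or a
#'   character vector of ranked cells.
#' @return The rank-1 cell id, or `NA_character_` when the ranking is
#'   empty.
#' @export
top_home_cell <- function(assignment) {
  cells <- if (inherits(assignment, "home_assignment")) {
    assignment$ranked_home_cells
  } else {
    as.character(assignment)
  }
  if (length(cells) == 0L) NA_character_ else cells[[1L]]
}

#' Infer ranked home cells for every subscriber-night
#'
#' Vectorized form of [infer_home_cells()] over a full event table:
#' night events are counted per (subscriber, night, cell) and the top
#' `n_home_cells` cells are ranked per subscriber-night, with the
#' deterministic tie-break on `cell_id`. Subscriber-nights with no night
#' events simply do not appear; downstream indicators that need a home
#' are emitted as missing for those days.
#'
#' @param events Sorted event table.
#' @param config A [study_config()].
#' @return A `data.table` with columns `subscriber_id`, `date` (the night
#'   date), `rank`, `cell_id`, `night_event_count` (total night events of
#'   that subscriber-night).
#' @export
infer_homes <- function(events, config = study_config()) {
  night <- night_filter(events, config)
  if (nrow(night) == 0L) {
    return(data.table::data.table(
      subscriber_id = character(0), date = as.IDate(integer(0)),
      rank = integer(0), cell_id = character(0), night_event_count = integer(0)
    ))
  }
  counts <- night[, .(n = .N), by = .(subscriber_id, date = night_date, cell_id)]
  counts[, night_event_count := sum(n), by = .(subscriber_id, date)]
  data.table::setorder(counts, subscriber_id, date, -n, cell_id)
  counts[, rank := seq_len(.N), by = .(subscriber_id, date)]
  out <- counts[rank <= config$n_home_cells,
                .(subscriber_id, date, rank, cell_id, night_event_count)]
  out[]
}

# rank-1 home per subscriber-night, as a plain table
top_homes <- function(homes) {
  homes[rank == 1L, .(subscriber_id, date, home_cell = cell_id)]
}

# subscriber-date -> set of ranked home cells, long form
home_cell_sets <- function(homes) {
  homes[, .(subscriber_id, date, cell_id)]
}
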