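#' Baseline values per group
#'
#' The baseline is the arithmetic mean of the unsuppressed values in the
#' baseline window (by default the first `moving_average_days` calendar
#' days of the series, which corresponds to the pre-pandemic reference
#' week when the series starts there). Groups whose window is entirely
#' suppressed or absent get a missing baseline and are excluded
#' downstream with a warning.
#'
#' @param agg Long aggregate table (`date`, grouping columns, `value`,
#'   `suppressed`).
#' @param config A [study_config()]; `baseline_window` and
#'   `moving_average_days` are consulted.
#' @param group_cols Grouping columns (default `region_id` and `kpi`).
#' @return Per-group `data.table` with a `baseline` column.
#' @export
compute_baseline <- function(agg, config = study_config(),
                             group_cols = c("region_id", "kpi")) {
  if (nrow(agg) == 0L) stop("empty aggregate table", call. = FALSE)
  win <- config$baseline_window
  if (is.null(win)) {
    d0 <- min(as.Date(agg$date))
    win <- c(d0, d0 + config$moving_average_days - 1L)
  }
  in_win <- as.Date(agg$date) >= win[1] & as.Date(agg$date) <= win[2]
  if (!any(in_win)) stop("baseline window contains no data", call. = FALSE)
  base <- agg[in_win & suppressed == FALSE & !is.na(value),
              .(baseline = mean(value)), by = group_cols]
  out <- merge(unique(agg[, group_cols, with = FALSE]), base,
               by = group_cols, all.x = TRUE)
  if (anyNA(out$baseline)) {
    warning(sum(is.na(out$baseline)),
            " group(s) have no unsuppressed baseline value and are excluded",
            call. = FALSE)
  }
  out
}

#' Percent change from baseline
#'
#' `100 * (value - baseline) / baseline`; suppressed or missing inputs
#' and missing or zero baselines propagate as missing (a zero baseline
#' additionally warns).
#'
#' @param agg Long aggregate table.
#' @param baselines Output of [compute_baseline()].
#' @param group_cols Grouping columns.
#' @return `agg` with `baseline` and `pct_change` columns.
#' @export
pct_change_from_baseline <- function(agg, baselines,
                                     group_cols = c("region_id", "kpi")) {
  out <- merge(agg, baselines, by = group_cols, all.x = TRUE)
  if (any(!is.na(out$baseline) & out$baseline == 0)) {
    warning("zero baseline(s); percent change set to missing", call. = FALSE)
  }
  out[, pct_change := ifelse(
    is.na(baseline) | baseline == 0 | is.na(value) | suppressed,
    NA_real_, 100 * (value - baseline) / baseline
  )]
  out[]
}

#' Trailing moving average over calendar days
#'
#' Averages the last `window_days` *calendar* days (trailing, including
#' the current day). The value is defined only where the full window is
#' available and unsuppressed: the date grid is completed first, so gaps
#' and suppressed days poison every window that touches them.
#'
#' @param x Table with `date`, `pct_change` and grouping columns.
#' @param window_days Window length in days (default 7).
#' @param group_cols Grouping columns.
#' @param value_col Column to smooth (default `"pct_change"`).
#' @return `x` on the completed date grid with a
#'   `smoothed_<value_col>` column.
#' @export
moving_average <- function(x, window_days = 7L,
                           group_cols = c("region_id", "kpi"),
                           value_col = "pct_change") {
  x <- data.table::copy(x)
  x[, date := as.IDate(date)]
  full <- x[, data.table::CJ(date = seq(min(date), max(date), by = 1L)),
            by = group_cols]
  out <- x[full, on = c(group_cols, "date")]
  data.table::setorderv(out, c(group_cols, "date"))
  smooth_col <- paste0("smoothed_", value_col)
  out[, (smooth_col) := data.table::frollmean(.SD[[1L]], window_days,
                                              align = "right"),
      .SDcols = value_col, by = group_cols]
  out[]
}

#' Build baseline-normalized trend series from aggregates
#'
#' The headline presentation: each aggregate series becomes its percent
#' difference from the baseline window mean, smoothed with a trailing
#' moving average.
#'
#' @param agg Long aggregate table from [aggregate_kpis_by_region()].
#' @param config A [study_config()].
#' @param group_cols Grouping columns.
#' @return A `data.table` with `region_id`, `kpi`, `date`, `raw_value`,
#'   `baseline`, `pct_change`, `smoothed_pct_change`, `suppressed`.
#' @export
compute_trends <- function(agg, config = study_config(),
                           group_cols = c("region_id", "kpi")) {
  baselines <- compute_baseline(agg, config, group_cols)
  pc <- pct_change_from_baseline(agg, baselines, group_cols)
  sm <- moving_average(pc, config$moving_average_days, group_cols)
  sm[is.na(suppressed), suppressed := TRUE]   # grid-completed gaps
  out <- sm[, c(group_cols, "date", "value", "baseline", "pct_change",
                "smoothed_pct_change", "suppressed"), with = FALSE]
  data.table::setnames(out, "value", "raw_value")
  data.table::setorderv(out, c(group_cols, "date"))
  out[]
}
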