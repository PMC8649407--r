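#' Replace subscriber identifiers with random pseudonyms
#'
#' Every distinct input id is mapped to one fresh random token; the
#' mapping is injective, lives only in this process and is never
#' returned or written anywhere. The draw is deterministic for a given
#' seed so pipeline runs are reproducible.
#'
#' @param events Event table.
#' @param seed Integer seed for the token draw.
#' @return The event table with `subscriber_id` replaced by pseudonyms.
#' @export
pseudonymize <- function(events, seed = 1L) {
  ids <- unique(events$subscriber_id)
  set.seed(seed)
  # sampling without replacement from a 2^31 space guarantees injectivity
  tokens <- sprintf("p%08x", sample.int(.Machine$integer.max, length(ids)))
  out <- data.table::copy(events)
  out[, subscriber_id := tokens[match(subscriber_id, ids)]]
  out[]
}

#' Apply k-anonymity suppression to an aggregate table
#'
#' Rows contributed to by fewer than `k` distinct subscribers are
#' flagged `suppressed` and their value columns are nulled, so the
#' exported artifact represents them as missing data. The contributing
#' count must already be a count of distinct subscribers, not of rows.
#'
#' @param agg Aggregate table with a `contributing_subscribers` column.
#' @param k Anonymity threshold (default 50); values below 1 are fatal.
#' @param value_cols Character vector of columns to null when
#'   suppressing; defaults to every numeric column other than
#'   `contributing_subscribers`.
#' @return The table with a `suppressed` logical column and nulled
#'   values.
#' @export
suppress <- function(agg, k = 50L, value_cols = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!"contributing_subscribers" %in% names(agg)) {
    stop("aggregate table lacks a contributing_subscribers column", call. = FALSE)
  }
  out <- data.table::copy(agg)
  if (is.null(value_cols)) {
    value_cols <- setdiff(
      names(out)[vapply(out, is.numeric, logical(1))],
      c("contributing_subscribers")
    )
  }
  out[, suppressed := contributing_subscribers < k]
  for (col in value_cols) {
    out[suppressed == TRUE, (col) := NA]
  }
  out[]
}

#' Aggregate daily indicators to region and country level
#'
#' Each subscriber-day is attributed to the region of the subscriber's
#' rank-1 home cell for that date. Per region, date and indicator, the
#' mean over non-missing subscriber-days is computed together with the
#' count of distinct contributing subscribers; a pooled country-level
#' aggregate (`region_id = "ALL"`) is always emitted too. k-anonymity
#' suppression is then applied uniformly.
#'
#' @param kpis Per subscriber-day table from [compute_daily_kpis()].
#' @param homes Home table from [infer_homes()].
#' @param registry Cell registry.
#' @param config A [study_config()]; supplies `k_anonymity`.
#' @return Long `data.table`: `date`, `region_id`, `kpi`, `value`,
#'   `contributing_subscribers`, `suppressed`.
#' @export
aggregate_kpis_by_region <- function(kpis, homes, registry,
                                     config = study_config()) {
  th <- top_homes(homes)
  th[, region_id := registry$region_id[match(home_cell, registry$cell_id)]]
  x <- th[, .(subscriber_id, date, region_id)][kpis, on = .(subscriber_id, date)]

  kpi_cols <- c("pct_time_home", "rog_km", "n_cells_visited",
                "collocation_exposure")
  kpi_cols <- intersect(kpi_cols, names(x))
  for (col in kpi_cols) data.table::set(x, j = col, value = as.numeric(x[[col]]))
  long <- data.table::melt(
    x, id.vars = c("subscriber_id", "date", "region_id"),
    measure.vars = kpi_cols, variable.name = "kpi", value.name = "value",
    variable.factor = FALSE
  )
  long <- long[!is.na(value)]

  by_region <- long[!is.na(region_id), .(
    value = mean(value),
    contributing_subscribers = data.table::uniqueN(subscriber_id)
  ), by = .(date, region_id, kpi)]
  country <- long[, .(
    value = mean(value),
    contributing_subscribers = data.table::uniqueN(subscriber_id)
  ), by = .(date, kpi)]
  country[, region_id := "ALL"]

  out <- data.table::rbindlist(list(by_region, country), use.names = TRUE)
  data.table::setcolorder(out, c("date", "region_id", "kpi", "value",
                                 "contributing_subscribers"))
  out <- suppress(out, config$k_anonymity, value_cols = "value")
  data.table::setorder(out, date, region_id, kpi)
  out[]
}

#' Audit an export directory for privacy leaks
#'
#' Scans every CSV under `dir` and reports three classes of violation:
#' (1) any appearance of an original subscriber id, (2) any per-row
#' subscriber identifier column at all (exports must be aggregates), and
#' (3) any row whose `contributing_subscribers` is below `k` yet is not
#' suppressed, or is suppressed but still carries a value.
#'
#' @param dir Directory of exported aggregates.
#' @param original_ids Character vector of raw subscriber ids that must
#'   not appear anywhere (optional).
#' @param k Anonymity threshold the exports claim to honour.
#' @return A list of class `mobikit_audit` with `ok` and a character
#'   vector of `violations`.
#' @export
audit_exports <- function(dir, original_ids = character(0), k = 50L) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE,
                      recursive = TRUE)
  violations <- character(0)
  for (f in files) {
    txt <- readLines(f, warn = FALSE)
    if (length(original_ids)) {
      hits <- original_ids[vapply(original_ids,
                                  function(id) any(grepl(id, txt, fixed = TRUE)),
                                  logical(1))]
      if (length(hits)) {
        violations <- c(violations, paste0(basename(f), ": contains original id(s) ",
                                           paste(head(hits, 5), collapse = ", ")))
      }
    }
    dt <- suppressWarnings(data.table::fread(f, showProgress = FALSE))
    if ("subscriber_id" %in% names(dt)) {
      violations <- c(violations,
                      paste0(basename(f), ": per-subscriber rows in export"))
    }
    count_col <- intersect(c("contributing_subscribers", "raw_count"), names(dt))[1]
    if (!is.na(count_col)) {
      sup <- if ("suppressed" %in% names(dt)) dt$suppressed else rep(FALSE, nrow(dt))
      counts <- dt[[count_col]]
      low_unsup <- !is.na(counts) & counts < k & !sup
      if (any(low_unsup)) {
        violations <- c(violations,
                        paste0(basename(f), ": ", sum(low_unsup),
                               " unsuppressed row(s) below k = ", k))
      }
      leak_cols <- intersect(c("value", "raw_count", "scaled_count"), names(dt))
      for (col in leak_cols) {
        if (any(sup & !is.na(dt[[col]]))) {
          violations <- c(violations,
                          paste0(basename(f), ": suppressed row(s) carry ", col))
        }
      }
    }
  }
  out <- list(ok = length(violations) == 0L, violations = violations,
              n_files = length(files))
  class(out) <- "mobikit_audit"
  out
}

#' @export
print.mobikit_audit <- function(x, ...) {
  cat("<mobikit_audit> ", if (x$ok) "CLEAN" else "VIOLATIONS", " (",
      x$n_files, " file(s) scanned)\n", sep = "")
  for (v in x$violations) cat("  - ", v, "\n", sep = "")
  invisible(x)
}
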