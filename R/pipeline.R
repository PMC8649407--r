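#' Run the full mobility-insights pipeline
#'
#' Orchestrates ingest, validation, pseudonymization, home inference,
#' the four daily indicators, origin-destination matrices with
#' population scaling, k-anonymous aggregation and baseline-normalized
#' trends, and writes everything to `out_dir`:
#'
#' * `internal/homes.csv`, `internal/kpis.csv` — per-subscriber tables
#'   carrying only pseudonyms; kept out of the export set because
#'   individual-level traces are never published.
#' * `export/kpi_aggregates.csv`, `export/od.csv`, `export/trends.csv`
#'   — the publishable, k-anonymously suppressed aggregates.
#' * `export/manifest.json` — configuration fingerprint, seed and row
#'   counts, for reproducibility.
#'
#' Identical inputs, configuration and seed produce byte-identical
#' output directories.
#'
#' @param events Event table or path to an events CSV.
#' @param cells Cell registry table or path.
#' @param population Region population table or path.
#' @param config A [study_config()].
#' @param out_dir Output directory (created).
#' @param seed Integer seed for pseudonymization.
#' @param drop_unknown_cells If `TRUE`, events referencing unknown cells
#'   are dropped (and counted) instead of aborting the run.
#' @return Invisibly, a list with all in-memory tables (`homes`, `kpis`,
#'   `od`, `aggregates`, `trends`, `scaling`, `validation`, `manifest`).
#' @export
run_pipeline <- function(events, cells, population,
                         config = study_config(), out_dir,
                         seed = 1L, drop_unknown_cells = FALSE) {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  registry <- step("ingest", {
    if (is.character(cells)) read_cell_registry(cells) else data.table::as.data.table(cells)
  })
  pop <- step("ingest", {
    if (is.character(population)) read_population(population) else data.table::as.data.table(population)
  })
  ev <- step("ingest", {
    if (is.character(events)) read_events(events, config) else data.table::as.data.table(events)
  })
  original_ids <- unique(ev$subscriber_id)

  report <- step("validate", validate_dataset(ev, registry, pop))
  if (report$n_unknown_cell_events > 0L) {
    if (!drop_unknown_cells) {
      stop("pipeline stage 'validate' failed: ", report$n_unknown_cell_events,
           " event(s) reference unknown cells (set drop_unknown_cells = TRUE to drop them)",
           call. = FALSE)
    }
    message("run_pipeline: dropping ", report$n_unknown_cell_events,
            " unknown-cell event(s)")
    ev <- ev[cell_id %in% registry$cell_id]
  }
  if (length(report$missing_population_regions)) {
    stop("pipeline stage 'validate' failed: regions without population: ",
         paste(report$missing_population_regions, collapse = ", "), call. = FALSE)
  }

  ev <- step("pseudonymize", pseudonymize(ev, seed))

  homes <- step("homes", infer_homes(ev, config))
  kpis <- step("kpis", compute_daily_kpis(ev, homes, registry, config))

  od_raw <- step("od", build_od_matrix(ev, registry, config))
  scaling <- step("od", suppressWarnings(compute_scaling(homes, registry, pop)))
  od <- step("od", scale_od_matrix(od_raw, scaling))
  od <- step("suppress", suppress(od, config$k_anonymity,
                                  value_cols = c("raw_count", "scaled_count")))

  agg <- step("aggregate", aggregate_kpis_by_region(kpis, homes, registry, config))
  trends <- step("trends", suppressWarnings(compute_trends(agg, config)))

  dir.create(file.path(out_dir, "internal"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "export"), recursive = TRUE, showWarnings = FALSE)

  step("write", {
    write_output_csv(homes, file.path(out_dir, "internal", "homes.csv"))
    write_output_csv(kpis, file.path(out_dir, "internal", "kpis.csv"))
    write_output_csv(agg, file.path(out_dir, "export", "kpi_aggregates.csv"))
    od_export <- od[, .(date, origin_region, destination_region,
                        raw_count, scaled_count, suppressed)]
    write_output_csv(od_export, file.path(out_dir, "export", "od.csv"))
    write_output_csv(trends, file.path(out_dir, "export", "trends.csv"))
  })

  manifest <- list(
    tool = "mobikit",
    version = as.character(utils::packageVersion("mobikit")),
    seed = seed,
    config = jsonlite::fromJSON(config_as_json(config)),
    config_hash = fnv1a_hash(config_as_json(config)),
    row_counts = list(
      events = nrow(ev),
      homes = nrow(homes),
      kpis = nrow(kpis),
      od = nrow(od),
      kpi_aggregates = nrow(agg),
      trends = nrow(trends)
    ),
    date_range = as.character(range(as.Date(ts_date(ev$timestamp))))
  )
  step("write", jsonlite::write_json(
    manifest, file.path(out_dir, "export", "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  ))

  audit <- step("audit", audit_exports(file.path(out_dir, "export"),
                                       original_ids = original_ids,
                                       k = config$k_anonymity))
  if (!audit$ok) {
    stop("pipeline stage 'audit' failed: ",
         paste(audit$violations, collapse = "; "), call. = FALSE)
  }

  invisible(list(
    events = ev, homes = homes, kpis = kpis, od = od, scaling = scaling,
    aggregates = agg, trends = trends, validation = report,
    manifest = manifest, audit = audit
  ))
}
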