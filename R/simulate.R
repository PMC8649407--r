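#' Define a synthetic mobility scenario
#'
#' A scenario fixes everything the generator needs: the world geometry
#' (regions and cell density), the subscriber panel, the observation
#' window, the behavioral model (home anchoring at night, distance-decay
#' day excursions) and a lockdown change-point that multiplies the
#' excursion scale by `mobility_reduction` from `lockdown_date` onward.
#'
#' Defaults emulate a small national footprint observed over four weeks
#' starting 1 February 2020 with a lockdown at the start of week three:
#' four administrative regions of roughly 30 km across with urban-grade
#' cell density (about 2.5 km between sites), an exponential excursion
#' kernel with an 8 km scale, and a sparse active-event sampling regime.
#'
#' @param n_regions Number of disjoint regions (default 4).
#' @param cells_per_region Cells per (urban) region (default 150). The
#'   last `rural_regions` regions get one third of that, reflecting the
#'   sparser tower grids of rural areas.
#' @param rural_regions How many trailing regions are rural (default 0).
#' @param n_subscribers Panel size (default 2000).
#' @param start_date,end_date Observation window, inclusive.
#' @param lockdown_date Date from which the excursion scale is multiplied
#'   by `mobility_reduction`; `NULL` disables the change-point.
#' @param mobility_reduction Multiplier in \[0, 1\] applied to the
#'   excursion kernel scale from `lockdown_date` onward (default 0.3).
#' @param sampling_regime One of `"cdr_sparse"` (active events only),
#'   `"probe_dense"` (passive signalling, `probe_rate_factor` times the
#'   sparse rate) or `"app_subset"` (sparse rate, but only a consented
#'   fraction of the panel is observed).
#' @param events_per_day_mean Mean events per subscriber-day under the
#'   sparse regime (default 8).
#' @param probe_rate_factor Rate multiplier for `"probe_dense"`
#'   (default 5).
#' @param app_consent_fraction Fraction of subscribers observed under
#'   `"app_subset"` (default 0.3).
#' @param night_home_prob Probability that a night-window event is served
#'   by the subscriber's true home cell (default 0.9); otherwise one of
#'   the three nearest neighbouring cells serves it, emulating tower
#'   load-balancing.
#' @param excursion_scale_km Scale (mean) of the exponential displacement
#'   kernel for daytime excursion destinations, in km (default 8).
#' @param destinations_per_day_mean Mean number of excursion destinations
#'   per subscriber-day (Poisson, floored at 1; default 3).
#' @param day_home_prob Probability that a daytime event is served by the
#'   home cell rather than an excursion destination (default 0.35).
#' @param region_size_km Side of each square region, in km (default 30).
#' @param persons_per_cell Population drawn per cell when building the
#'   region population table (default 1000).
#' @param relocation_date Optional date on which a fraction of
#'   subscribers permanently switch home cell (default `NULL`, off).
#' @param relocation_fraction Fraction relocating when `relocation_date`
#'   is set (default 0.05).
#' @param rng_seed Integer seed making the whole generation deterministic.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_regions = 4L,
                         cells_per_region = 150L,
                         rural_regions = 0L,
                         n_subscribers = 2000L,
                         start_date = "2020-02-01",
                         end_date = "2020-02-28",
                         lockdown_date = "2020-02-15",
                         mobility_reduction = 0.3,
                         sampling_regime = c("cdr_sparse", "probe_dense", "app_subset"),
                         events_per_day_mean = 8,
                         probe_rate_factor = 5,
                         app_consent_fraction = 0.3,
                         night_home_prob = 0.9,
                         excursion_scale_km = 8,
                         destinations_per_day_mean = 3,
                         day_home_prob = 0.35,
                         region_size_km = 30,
                         persons_per_cell = 1000,
                         relocation_date = NULL,
                         relocation_fraction = 0.05,
                         rng_seed = 1L) {
  sampling_regime <- match.arg(sampling_regime)
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (!is.null(lockdown_date)) lockdown_date <- as.Date(lockdown_date)
  if (!is.null(relocation_date)) relocation_date <- as.Date(relocation_date)

  stopifnot(
    n_regions >= 1, cells_per_region >= 1, n_subscribers >= 1,
    rural_regions >= 0, rural_regions <= n_regions,
    start_date <= end_date,
    mobility_reduction >= 0, mobility_reduction <= 1,
    night_home_prob >= 0, night_home_prob <= 1,
    app_consent_fraction > 0, app_consent_fraction <= 1,
    events_per_day_mean > 0, probe_rate_factor >= 1,
    excursion_scale_km > 0, region_size_km > 0, persons_per_cell > 0,
    destinations_per_day_mean > 0, day_home_prob >= 0, day_home_prob <= 1
  )
  if (!is.null(lockdown_date) &&
      (lockdown_date < start_date || lockdown_date > end_date)) {
    stop("lockdown_date must lie within [start_date, end_date]", call. = FALSE)
  }

  sc <- list(
    n_regions = as.integer(n_regions),
    cells_per_region = as.integer(cells_per_region),
    rural_regions = as.integer(rural_regions),
    n_subscribers = as.integer(n_subscribers),
    start_date = start_date, end_date = end_date,
    lockdown_date = lockdown_date,
    mobility_reduction = mobility_reduction,
    sampling_regime = sampling_regime,
    events_per_day_mean = events_per_day_mean,
    probe_rate_factor = probe_rate_factor,
    app_consent_fraction = app_consent_fraction,
    night_home_prob = night_home_prob,
    excursion_scale_km = excursion_scale_km,
    destinations_per_day_mean = destinations_per_day_mean,
    day_home_prob = day_home_prob,
    region_size_km = region_size_km,
    persons_per_cell = persons_per_cell,
    relocation_date = relocation_date,
    relocation_fraction = relocation_fraction,
    rng_seed = as.integer(rng_seed)
  )
  class(sc) <- "sim_scenario"
  sc
}

# Approximate km-per-degree at the reference latitude used to lay the
# world out; excursions are planar, distances are later realized on the
# sphere through the cell coordinates.
KM_PER_DEG_LAT <- 110.574
REF_LAT <- 40

km_per_deg_lon <- function(lat) 111.320 * cos(lat * pi / 180)

#' Generate the synthetic world: cell registry and region populations
#'
#' Regions are disjoint square boxes on a grid (with a gap of 20% of the
#' box side, so stationary subscribers can never straddle a boundary);
#' cells are placed uniformly inside each box. Region population is
#' proportional to cell count with a +/-10% perturbation.
#'
#' @param scenario A [sim_scenario()].
#' @return A list with `cells` (cell registry `data.table`) and
#'   `population` (region population `data.table`). Deterministic for a
#'   fixed `rng_seed`.
#' @export
generate_world <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$rng_seed)

  n_r <- scenario$n_regions
  box_lat <- scenario$region_size_km / KM_PER_DEG_LAT
  box_lon <- scenario$region_size_km / km_per_deg_lon(REF_LAT)
  pitch_lat <- 1.2 * box_lat
  pitch_lon <- 1.2 * box_lon
  n_col <- ceiling(sqrt(n_r))

  n_cells_region <- rep(scenario$cells_per_region, n_r)
  if (scenario$rural_regions > 0L) {
    rural <- seq.int(n_r - scenario$rural_regions + 1L, n_r)
    n_cells_region[rural] <- pmax(1L, ceiling(scenario$cells_per_region / 3))
  }

  cells <- vector("list", n_r)
  next_id <- 1L
  for (i in seq_len(n_r)) {
    row <- (i - 1L) %/% n_col
    col <- (i - 1L) %% n_col
    lat0 <- REF_LAT + row * pitch_lat
    lon0 <- col * pitch_lon
    k <- n_cells_region[i]
    cells[[i]] <- data.table::data.table(
      cell_id = sprintf("C%05d", seq.int(next_id, next_id + k - 1L)),
      lat = lat0 + runif(k) * box_lat,
      lon = lon0 + runif(k) * box_lon,
      region_id = sprintf("R%02d", i)
    )
    next_id <- next_id + k
  }
  cells <- data.table::rbindlist(cells)

  population <- cells[, .(n_cells = .N), by = region_id]
  population[, population := pmax(1L, as.integer(round(
    n_cells * scenario$persons_per_cell * runif(.N, 0.9, 1.1)
  )))]
  population[, n_cells := NULL]

  data.table::setkey(cells, cell_id)
  data.table::setkey(population, region_id)
  list(cells = cells[], population = population[])
}

# Planar km coordinates of the registry (equirectangular about REF_LAT)
cells_xy <- function(cells) {
  data.table::data.table(
    cell_id = cells$cell_id,
    x_km = cells$lon * km_per_deg_lon(REF_LAT),
    y_km = cells$lat * KM_PER_DEG_LAT
  )
}

# Nearest cell (index into xy) for each target point, chunked so the
# point-by-cell distance matrix stays small.
snap_to_cells <- function(x, y, xy, chunk = 50000L) {
  n <- length(x)
  out <- integer(n)
  cx <- xy$x_km
  cy <- xy$y_km
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    d2 <- outer(x[lo:hi], cx, "-")^2 + outer(y[lo:hi], cy, "-")^2
    out[lo:hi] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Simulate an event stream with known ground truth
#'
#' Each subscriber gets a fixed true home cell. Movement is trip-based:
#' every active subscriber-day draws a small Poisson number of excursion
#' destinations from an exponential distance-decay kernel around home
#' (the kernel scale is multiplied by `mobility_reduction` from
#' `lockdown_date` onward) and each destination is snapped to its
#' nearest cell site. Event counts per subscriber-day are Poisson with a
#' regime-dependent rate and event times are uniform over the day.
#' Night-window events are served by the home cell with probability
#' `night_home_prob`, otherwise by one of the three nearest neighbouring
#' cells (tower load-balancing); daytime events are served by the home
#' cell with probability `day_home_prob`, otherwise by a uniformly
#' chosen destination of that day.
#'
#' @param scenario A [sim_scenario()].
#' @param world The output of [generate_world()] for the same scenario.
#' @param config A [study_config()]; supplies the night window.
#' @return A list with `events` (sorted event `data.table`) and `truth`,
#'   itself a list of `homes` (`subscriber_id`, `true_home_cell_id`) and
#'   `daily` (per subscriber-day: `true_rms_km`, the root-mean-square of
#'   the continuous destination displacements before cell snapping — the
#'   quantity the radius of gyration estimates — and
#'   `n_excursion_cells`, the number of distinct destination cells).
#'   Deterministic for a fixed `rng_seed`.
#' @export
simulate_events <- function(scenario, world, config = study_config()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed((scenario$rng_seed %% .Machine$integer.max) + 1L)

  cells <- world$cells
  xy <- cells_xy(cells)
  n_cells <- nrow(cells)

  # up to 3 nearest same-region neighbours of every cell, for off-home
  # night events (overlapping coverage is local, so a night hand-off
  # never leaves the home region)
  k_nb <- max(1L, min(3L, n_cells - 1L))
  nb <- matrix(rep(seq_len(n_cells), k_nb), n_cells, k_nb)
  d2 <- outer(xy$x_km, xy$x_km, "-")^2 + outer(xy$y_km, xy$y_km, "-")^2
  diag(d2) <- Inf
  d2[outer(cells$region_id, cells$region_id, "!=")] <- Inf
  for (j in seq_len(n_cells)) {
    cand <- which(is.finite(d2[j, ]))
    if (length(cand)) {
      cand <- cand[order(d2[j, cand])]
      nb[j, ] <- cand[pmin(seq_len(k_nb), length(cand))]
    }  # single-cell region: neighbour stays the cell itself
  }

  subs <- sprintf("U%06d", seq_len(scenario$n_subscribers))
  if (scenario$sampling_regime == "app_subset") {
    keep_n <- max(1L, round(scenario$app_consent_fraction * length(subs)))
    subs <- sort(sample(subs, keep_n))
  }
  n_sub <- length(subs)
  home_idx <- sample.int(n_cells, n_sub, replace = TRUE)

  dates <- seq(scenario$start_date, scenario$end_date, by = "day")
  n_day <- length(dates)

  rate <- scenario$events_per_day_mean *
    switch(scenario$sampling_regime,
           cdr_sparse = 1, probe_dense = scenario$probe_rate_factor,
           app_subset = 1)

  # one row per active (subscriber, day)
  grid <- data.table::CJ(sub = seq_len(n_sub), day = seq_len(n_day))
  grid[, n_events := rpois(.N, rate)]
  grid <- grid[n_events > 0L]
  grid[, gidx := .I]

  # optional permanent relocation: a fraction of subscribers switch home
  home_of <- function(sub_i, day_i) home_idx[sub_i]
  if (!is.null(scenario$relocation_date)) {
    movers <- runif(n_sub) < scenario$relocation_fraction
    new_home <- sample.int(n_cells, n_sub, replace = TRUE)
    reloc_day <- as.integer(scenario$relocation_date - scenario$start_date) + 1L
    home_of <- function(sub_i, day_i) {
      ifelse(movers[sub_i] & day_i >= reloc_day, new_home[sub_i], home_idx[sub_i])
    }
  }
  grid[, home_cell := home_of(sub, day)]

  # excursion destinations per active subscriber-day, kernel scale
  # shrunk by mobility_reduction from the lockdown day onward
  grid[, n_dest := pmax(1L, rpois(.N, scenario$destinations_per_day_mean))]
  if (is.null(scenario$lockdown_date)) {
    grid[, day_scale := scenario$excursion_scale_km]
  } else {
    lock_day <- as.integer(scenario$lockdown_date - scenario$start_date) + 1L
    grid[, day_scale := scenario$excursion_scale_km *
           ifelse(day >= lock_day, scenario$mobility_reduction, 1)]
  }
  dest <- data.table::data.table(
    gidx = rep(grid$gidx, grid$n_dest),
    home_cell = rep(grid$home_cell, grid$n_dest),
    r = rexp(sum(grid$n_dest)) * rep(grid$day_scale, grid$n_dest),
    theta = runif(sum(grid$n_dest), 0, 2 * pi)
  )
  dest[, cell_idx := snap_to_cells(xy$x_km[home_cell] + r * cos(theta),
                                   xy$y_km[home_cell] + r * sin(theta), xy)]
  dest_offset <- cumsum(grid$n_dest) - grid$n_dest  # 0-based start per gidx

  ev <- grid[rep(seq_len(.N), n_events), .(gidx, sub, day, home_cell)]
  n_ev <- nrow(ev)
  ev[, minute_of_day := sample.int(1440L, n_ev, replace = TRUE) - 1L]
  ev[, second_of_day := minute_of_day * 60L + sample.int(60L, n_ev, replace = TRUE) - 1L]

  ns <- config$night_start_min
  ne <- config$night_end_min
  ev[, is_night := if (ns > ne) minute_of_day >= ns | minute_of_day < ne
                   else minute_of_day >= ns & minute_of_day < ne]

  # night events: home with prob night_home_prob, else a nearby cell
  ev[, cell_idx := home_cell]
  night <- which(ev$is_night)
  if (length(night)) {
    off <- night[runif(length(night)) >= scenario$night_home_prob]
    if (length(off)) {
      pick <- nb[cbind(ev$home_cell[off],
                       sample.int(k_nb, length(off), replace = TRUE))]
      ev[off, cell_idx := pick]
    }
  }

  # day events: home with prob day_home_prob, else one of the day's
  # destinations, uniformly
  daytime <- which(!ev$is_night)
  if (length(daytime)) {
    at_dest <- daytime[runif(length(daytime)) >= scenario$day_home_prob]
    if (length(at_dest)) {
      g <- ev$gidx[at_dest]
      j <- 1L + as.integer(floor(runif(length(at_dest)) * grid$n_dest[g]))
      ev[at_dest, cell_idx := dest$cell_idx[dest_offset[g] + j]]
    }
  }

  ev[, `:=`(
    subscriber_id = subs[sub],
    timestamp = as.POSIXct(dates[day], tz = "UTC") + second_of_day,
    cell_id = cells$cell_id[cell_idx],
    date = as.IDate(dates[day])
  )]

  truth_daily <- dest[, .(
    true_rms_km = sqrt(mean(r^2)),
    n_excursion_cells = data.table::uniqueN(cell_idx)
  ), by = gidx]
  truth_daily <- grid[, .(gidx, subscriber_id = subs[sub],
                          date = as.IDate(dates[day]))][
    truth_daily, on = "gidx"][, gidx := NULL]
  truth_homes <- data.table::data.table(
    subscriber_id = subs,
    true_home_cell_id = cells$cell_id[home_idx]
  )
  truth_daily <- truth_homes[truth_daily, on = "subscriber_id"]
  data.table::setcolorder(truth_daily,
    c("subscriber_id", "date", "true_home_cell_id", "true_rms_km", "n_excursion_cells"))
  data.table::setorder(truth_daily, subscriber_id, date)

  events <- ev[, .(subscriber_id, timestamp, cell_id)]
  data.table::setorder(events, timestamp, subscriber_id, cell_id)

  list(events = events[],
       truth = list(homes = truth_homes[], daily = truth_daily[]))
}

#' Run a scenario and write its world, events and ground truth to disk
#'
#' Writes `events.csv`, `cells.csv`, `population.csv` and
#' `ground_truth.csv` (one row per subscriber-day with the true home cell
#' and true excursion RMS) under `out_dir`.
#'
#' @param scenario A [sim_scenario()].
#' @param out_dir Output directory, created if needed.
#' @param config A [study_config()].
#' @return Invisibly, the list returned by [simulate_events()] plus the
#'   world tables.
#' @export
run_simulation <- function(scenario, out_dir, config = study_config()) {
  world <- generate_world(scenario)
  sim <- simulate_events(scenario, world, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_events(sim$events, file.path(out_dir, "events.csv"))
  write_output_csv(world$cells, file.path(out_dir, "cells.csv"))
  write_output_csv(world$population, file.path(out_dir, "population.csv"))
  write_output_csv(sim$truth$daily, file.path(out_dir, "ground_truth.csv"))
  invisible(c(world, sim))
}
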