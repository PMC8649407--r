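homes_row <- function(sub, date, cells) {
  data.table(subscriber_id = sub, date = as.IDate(date),
             rank = seq_along(cells), cell_id = cells,
             night_event_count = length(cells))
}

test_that("haversine distance matches closed forms and is symmetric", {
  expect_equal(haversine_km(0, 0, 0, 0), 0)
  expect_equal(haversine_km(0, 0, 0, 90), 6371 * pi / 2, tolerance = 1e-12)
  expect_equal(haversine_km(0, 0, 90, 0), 6371 * pi / 2, tolerance = 1e-12)
  # the configured radius scales distances linearly
  expect_equal(haversine_km(0, 0, 0, 90, earth_radius_km = 3671),
               3671 * pi / 2, tolerance = 1e-12)
  expect_equal(haversine_km(12.3, 45.6, -7.8, 9.1),
               haversine_km(-7.8, 9.1, 12.3, 45.6))
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 181, 0, 0), "longitude")
})

test_that("haversine agrees with independent geodesic implementations", {
  set.seed(123)
  n <- 1000
  lat1 <- runif(n, -89, 89); lon1 <- runif(n, -179, 179)
  lat2 <- runif(n, -89, 89); lon2 <- runif(n, -179, 179)
  ours <- haversine_km(lat1, lon1, lat2, lon2)
  oracle <- law_of_cosines_km(lat1, lon1, lat2, lon2)
  expect_lt(max(abs(ours - oracle) / pmax(oracle, 1e-6)), 1e-9)

  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = 6371) # km
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("midpoint dwell allocation matches hand-worked cases", {
  cfg <- study_config()
  ev <- make_events(rep("s1", 2),
                    c("2020-03-01 08:00", "2020-03-01 10:00"), c("A", "A"))
  dw <- dwell_times(ev, cfg)
  expect_equal(dw$dwell$dwell_seconds, 2 * 3600)
  expect_equal(dw$totals$t_total_s, 2 * 3600)

  ev <- make_events(rep("s1", 3),
                    c("2020-03-01 08:00", "2020-03-01 10:00", "2020-03-01 12:00"),
                    c("A", "B", "B"))
  dw <- dwell_times(ev, cfg)
  got <- setNames(dw$dwell$dwell_seconds, dw$dwell$cell_id)
  expect_equal(got[["A"]], 1 * 3600)
  expect_equal(got[["B"]], 3 * 3600)
  expect_equal(dw$totals$t_total_s, 4 * 3600)

  single <- dwell_times(make_events("s1", "2020-03-01 08:00", "A"), cfg)
  expect_equal(single$totals$t_total_s, 0)
  expect_true(single$totals$degenerate)
})

test_that("dwell conserves observed time on random fixtures", {
  reg <- toy_registry()
  for (seed in 1:5) {
    ev <- random_day_events(reg, n = 120, n_sub = 6, seed = seed)
    dw <- dwell_times(ev, study_config())
    per_day <- dw$dwell[, .(s = sum(dwell_seconds)), by = .(subscriber_id, date)]
    chk <- merge(per_day, dw$totals, by = c("subscriber_id", "date"))
    expect_equal(chk$s, chk$t_total_s, tolerance = 1e-9)
    # and matches the event-by-event oracle
    one <- ev[subscriber_id == "s01"]
    oracle <- oracle_dwell(one$timestamp, one$cell_id)
    got <- dw$dwell[subscriber_id == "s01"]
    expect_equal(setNames(got$dwell_seconds, got$cell_id)[names(oracle$dwell)],
                 oracle$dwell, tolerance = 1e-9)
  }
})

test_that("percent time at home follows the dwell ratio over ranked home cells", {
  cfg <- study_config()
  # all dwell at the home cell
  ev <- make_events(rep("s1", 2), c("2020-03-01 08:00", "2020-03-01 18:00"),
                    c("A", "A"))
  dw <- dwell_times(ev, cfg)
  expect_equal(pct_time_home(dw, homes_row("s1", "2020-03-01", "A"))$pct_time_home, 1)

  # t_home 6h of t_total 8h
  ev <- make_events(rep("s1", 3),
                    c("2020-03-01 08:00", "2020-03-01 12:00", "2020-03-01 16:00"),
                    c("A", "A", "B"))
  dw <- dwell_times(ev, cfg)
  expect_equal(pct_time_home(dw, homes_row("s1", "2020-03-01", "A"))$pct_time_home,
               0.75)

  # dwell {A:1h, B:2h, C:1h} with homes [A, B] -> 0.75
  ev <- make_events(rep("s1", 3),
                    c("2020-03-01 08:00", "2020-03-01 10:00", "2020-03-01 12:00"),
                    c("A", "B", "C"))
  dw <- dwell_times(ev, cfg)
  expect_equal(
    pct_time_home(dw, homes_row("s1", "2020-03-01", c("A", "B")))$pct_time_home,
    0.75)

  # missing home assignment -> missing, not zero
  expect_true(is.na(
    pct_time_home(dw, homes_row("s9", "2020-03-01", "A"))$pct_time_home))

  # degenerate single-event day: membership of that event decides
  one <- dwell_times(make_events("s1", "2020-03-01 08:00", "A"), cfg)
  expect_equal(pct_time_home(one, homes_row("s1", "2020-03-01", "A"))$pct_time_home, 1)
  expect_equal(pct_time_home(one, homes_row("s1", "2020-03-01", "B"))$pct_time_home, 0)
})

test_that("radius of gyration is the RMS distance over distinct cells", {
  cfg <- study_config()
  reg <- registry_at_km(offsets_km = c(3, 4, 5), ids = c("K3", "K4", "K5"))
  homes <- homes_row("s1", "2020-03-01", "H")

  # all events at the home cell
  ev <- make_events(rep("s1", 3),
                    sprintf("2020-03-01 08:0%d", 0:2), rep("H", 3))
  expect_equal(radius_of_gyration(ev, homes, reg, cfg)$rog_km, 0)

  # distinct cells at 3 and 4 km -> sqrt((9 + 16) / 2)
  ev <- make_events(rep("s1", 2), c("2020-03-01 09:00", "2020-03-01 10:00"),
                    c("K3", "K4"))
  expect_equal(radius_of_gyration(ev, homes, reg, cfg)$rog_km,
               sqrt((9 + 16) / 2), tolerance = 1e-9)

  # multiplicity is ignored: one cell at 5 km visited ten times
  ev <- make_events(rep("s1", 10),
                    sprintf("2020-03-01 %02d:00", 8:17), rep("K5", 10))
  expect_equal(radius_of_gyration(ev, homes, reg, cfg)$rog_km, 5,
               tolerance = 1e-9)
  # ... and order does not matter
  ev2 <- ev[sample(.N)]
  expect_equal(radius_of_gyration(ev2, homes, reg, cfg),
               radius_of_gyration(ev, homes, reg, cfg))

  # missing home -> missing KPI
  expect_true(is.na(radius_of_gyration(
    ev, homes_row("s1", "2020-03-02", "H"), reg, cfg)$rog_km))
})

test_that("radius of gyration matches a brute-force oracle on random days", {
  reg <- toy_registry()
  homes <- homes_row("s01", "2020-03-01", "A")
  for (seed in 1:5) {
    ev <- random_day_events(reg, n = 60, n_sub = 1, seed = seed)
    got <- radius_of_gyration(ev, homes, reg, study_config())$rog_km
    want <- oracle_rog(ev$cell_id, "A", reg)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("distinct cells visited is the cardinality of the day's cell set", {
  ev <- make_events(rep("s1", 3),
                    c("2020-03-01 08:00", "2020-03-01 09:00", "2020-03-01 10:00"),
                    c("A", "A", "B"))
  expect_equal(distinct_cells_visited(ev)$n_cells_visited, 2L)

  reg <- toy_registry()
  ev <- random_day_events(reg, n = 200, n_sub = 4, seed = 9)
  got <- distinct_cells_visited(ev)
  for (s in unique(ev$subscriber_id)) {
    expect_equal(got[subscriber_id == s]$n_cells_visited,
                 length(unique(ev[subscriber_id == s]$cell_id)))
  }
})

test_that("collocation counts distinct non-home subscribers per cell-bucket", {
  cfg <- study_config()
  homes <- rbind(homes_row("s1", "2020-03-01", "A"),
                 homes_row("s2", "2020-03-01", "B"),
                 homes_row("s3", "2020-03-01", "C"))

  # one subscriber alone in a non-home cell -> exposure 1
  ev <- make_events("s1", "2020-03-01 10:15", "D")
  col <- collocation(ev, homes, cfg)
  expect_equal(col$exposure$collocation_exposure, 1)

  # only events at the own home cell -> excluded entirely
  ev <- make_events("s1", c("2020-03-01 10:15", "2020-03-01 11:20"), c("A", "A"))
  col <- collocation(ev, homes, cfg)
  expect_equal(nrow(col$exposure), 0L)

  # three subscribers in one cell and bucket, none home there -> each sees 3
  ev <- make_events(c("s1", "s2", "s3"),
                    c("2020-03-01 10:05", "2020-03-01 10:25", "2020-03-01 10:55"),
                    rep("D", 3))
  col <- collocation(ev, homes, cfg)
  expect_equal(col$exposure$collocation_exposure, rep(3, 3))
  expect_equal(col$cohorts$cohort, 3L)
})

test_that("collocation cohort counts equal the nested-loop oracle", {
  reg <- toy_registry()
  cfg <- study_config()
  for (seed in 1:3) {
    ev <- random_day_events(reg, n = 200, n_sub = 8, seed = seed)
    homes <- infer_homes(ev, cfg)
    got <- collocation(ev, homes, cfg)$cohorts
    want <- oracle_collocation_counts(ev, home_sets_of(homes))
    merged <- merge(got[, .(date = as.character(date), cell = cell_id,
                            bucket, cohort_got = cohort)],
                    want, by = c("date", "cell", "bucket"), all = TRUE)
    # keys the implementation omits must be exactly the zero-cohort ones
    merged[is.na(cohort_got), cohort_got := 0L]
    expect_equal(merged$cohort_got, merged$cohort)
  }
})

test_that("stronger lockdowns monotonically shift the population KPIs", {
  run_kpis <- function(reduction) {
    sc <- small_scenario(mobility_reduction = reduction, n_subscribers = 80L,
                         events_per_day_mean = 15)
    w <- generate_world(sc)
    sim <- simulate_events(sc, w)
    cfg <- study_config()
    homes <- infer_homes(sim$events, cfg)
    kpis <- compute_daily_kpis(sim$events, homes, w$cells, cfg)
    kpis[date >= as.IDate("2020-02-06"), .(
      rog = mean(rog_km, na.rm = TRUE),
      ncells = mean(n_cells_visited, na.rm = TRUE),
      home = mean(pct_time_home, na.rm = TRUE)
    )]
  }
  open <- run_kpis(1.0)
  locked <- run_kpis(0.3)
  expect_lt(locked$rog, open$rog)
  expect_lt(locked$ncells, open$ncells)
  expect_gt(locked$home, open$home)
})
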