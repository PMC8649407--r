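test_that("transitions collapse runs and deduplicate at person level", {
  reg <- toy_registry()  # A,B,C in R1; D,E in R2
  cfg <- study_config()

  # region sequence [R1, R1, R2] -> {(R1, R2)}
  ev <- make_events(rep("s1", 3),
                    sprintf("2020-03-01 %02d:00", 8:10), c("A", "B", "D"))
  tr <- extract_transitions(ev, reg, cfg)
  expect_equal(tr$origin_region, "R1")
  expect_equal(tr$destination_region, "R2")
  expect_equal(tr$n, 1L)

  # [R1, R2, R1, R2] -> both ordered pairs, each once
  ev <- make_events(rep("s1", 4),
                    sprintf("2020-03-01 %02d:00", 8:11), c("A", "D", "B", "E"))
  tr <- extract_transitions(ev, reg, cfg)
  expect_equal(nrow(tr), 2L)
  expect_setequal(paste(tr$origin_region, tr$destination_region),
                  c("R1 R2", "R2 R1"))
  expect_true(all(tr$n == 1L))

  # trips mode keeps multiplicity
  cfg_trips <- study_config(od_count_mode = "trips")
  ev <- make_events(rep("s1", 4),
                    sprintf("2020-03-01 %02d:00", 8:11), c("A", "D", "A", "D"))
  tr <- extract_transitions(ev, reg, cfg_trips)
  expect_equal(tr[origin_region == "R1"]$n, 2L)

  # stationary within one region -> no movement
  ev <- make_events(rep("s1", 3),
                    sprintf("2020-03-01 %02d:00", 8:10), c("A", "B", "A"))
  expect_equal(nrow(extract_transitions(ev, reg, cfg)), 0L)
})

test_that("the daily matrix tallies persons per ordered pair", {
  reg <- toy_registry()
  cfg <- study_config()
  ev <- make_events(
    rep(c("s1", "s2", "s3"), each = 2),
    rep(c("2020-03-01 08:00", "2020-03-01 12:00"), 3),
    c("A", "D", "B", "E", "C", "D")
  )
  od <- build_od_matrix(ev, reg, cfg)
  expect_equal(nrow(od), 1L)
  expect_equal(od$raw_count, 3L)
  expect_equal(od$contributing_subscribers, 3L)

  # no transitions at all -> empty matrix
  ev <- make_events("s1", c("2020-03-01 08:00", "2020-03-01 09:00"), c("A", "B"))
  expect_equal(nrow(build_od_matrix(ev, reg, cfg)), 0L)
})

test_that("matrix counts equal a brute-force per-subscriber tally", {
  reg <- toy_registry()
  cfg <- study_config()
  for (seed in 1:3) {
    ev <- random_day_events(reg, n = 200, n_sub = 10, seed = seed)
    od <- build_od_matrix(ev, reg, cfg)
    want <- oracle_od(ev, reg)
    expect_equal(nrow(od), length(want))
    for (i in seq_len(nrow(od))) {
      key <- paste0(od$date[i], "|", od$origin_region[i], ">",
                    od$destination_region[i])
      expect_equal(od$raw_count[i], want[[key]])
    }
    # dedup: no pair can exceed the subscriber count
    expect_true(all(od$raw_count <= data.table::uniqueN(ev$subscriber_id)))
  }
})

test_that("scaling multipliers divide population by resident subscribers", {
  reg <- toy_registry()
  pop <- data.table(region_id = c("R1", "R2"), population = c(1000L, 600L))
  # 100 subscribers with rank-1 home in R1 on the night of Feb 29
  homes <- data.table(
    subscriber_id = sprintf("s%03d", 1:103),
    date = as.IDate("2020-02-29"),
    rank = 1L,
    cell_id = c(rep("A", 100), rep("D", 3)),
    night_event_count = 5L
  )
  sc <- compute_scaling(homes, reg, pop)
  expect_equal(sc[region_id == "R1"]$customers_home, 100L)
  expect_equal(sc[region_id == "R1"]$multiplier, 10)
  expect_equal(sc[region_id == "R2"]$multiplier, 200)
  # multipliers apply to the following day
  expect_equal(unique(as.character(sc$date)), "2020-03-01")

  # a region with no resident subscribers gets a missing multiplier
  expect_warning(
    sc0 <- compute_scaling(homes[cell_id == "A"], reg, pop),
    "zero home subscribers")
  expect_true(is.na(sc0[region_id == "R2"]$multiplier))

  # a region absent from the population table is fatal
  expect_error(compute_scaling(homes, reg, pop[region_id != "R2"]),
               "missing from population")
})

test_that("scaled counts are the raw counts times the origin multiplier", {
  od <- data.table(
    date = as.IDate("2020-03-01"),
    origin_region = c("R1", "R2"),
    destination_region = c("R2", "R1"),
    raw_count = c(5L, 2L),
    contributing_subscribers = c(5L, 2L)
  )
  scaling <- data.table(
    date = as.IDate("2020-03-01"),
    region_id = c("R1", "R2"),
    customers_home = c(100L, 0L),
    multiplier = c(10, NA_real_)
  )
  scaled <- scale_od_matrix(od, scaling)
  expect_equal(scaled[origin_region == "R1"]$scaled_count, 50)
  expect_true(is.na(scaled[origin_region == "R2"]$scaled_count))

  # exact linearity in the multipliers
  scaling2 <- copy(scaling)[, multiplier := multiplier * 2]
  scaled2 <- scale_od_matrix(od, scaling2)
  expect_equal(scaled2$scaled_count, scaled$scaled_count * 2)
})

test_that("stationary subscribers near region interiors yield no spurious flows", {
  sc <- small_scenario(mobility_reduction = 0, n_subscribers = 25L,
                       lockdown_date = "2020-02-01")
  w <- generate_world(sc)
  sim <- simulate_events(sc, w)
  # with reduction 0 from day one, all day events sit on the home cell;
  # only the rare night neighbour hop can move a subscriber, and the
  # three nearest neighbours of an interior cell stay within its region
  od <- build_od_matrix(sim$events, w$cells, study_config())
  expect_equal(sum(od$raw_count), 0L)
})
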