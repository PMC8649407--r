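# mobikit

Privacy-preserving population-mobility analytics from pseudonymous
mobile-network sighting data.

Network operators log, for every active phone, a timestamp and the
serving cell. During an epidemic those logs are one of the few
population-scale measurements of behaviour that exist. `mobikit` turns
a sighting table `(subscriber_id, timestamp, cell_id)`, a cell-site
registry and a region population table into the standard
mobility-monitoring outputs used by public-health and policy teams —
while enforcing, by construction, that nothing individual-level is ever
exported.

## What it computes

For each subscriber and night (22:00–05:00 local), the **top-3 night
cells** ranked by event count approximate the home location. From these
and the day's events it derives, per subscriber-day:

* **Percent time at home** — `t_home / t_total`, the dwell time at the
  ranked home cells over the total time observed in the network
  (dwell allocated by midpoint-splitting the gaps between sightings);
* **Radius of gyration** —
  `ROG = sqrt( (1/N) * Σ_i d_i² )`, where `d_1 … d_N` are haversine
  great-circle distances from the `N` *distinct* cells visited that day
  to the rank-1 home cell (multiplicity of visits is ignored);
* **Distinct cells visited** — `N` itself;
* **Collocation exposure** — the mean number of distinct non-home
  subscribers sharing a cell with the subscriber within 60-minute
  clock buckets.

Daily **origin–destination matrices** count, once per subscriber-day,
each ordered pair of distinct adjacent regions in the subscriber's
collapsed region sequence, and scale the counts to population with the
per-region multiplier `population / resident_subscribers` (residency =
previous night's rank-1 home).

Every published aggregate is **k-anonymously suppressed** (`k = 50` by
default: fewer than 50 distinct contributors ⇒ exported as missing),
subscriber ids are re-pseudonymized in process, and an audit pass
verifies the export set before the pipeline returns. Aggregate series
are reported as **percent change from a baseline window** (default: the
series' first week) with a trailing **7-day moving average**.

Because no public data of this kind exists, the package includes a
synthetic generator (`sim_scenario()`, `simulate_events()`) with known
ground truth — fixed true homes, trip-based excursions with an
exponential distance kernel, and a lockdown change-point that shrinks
the excursion scale — so the whole pipeline is testable end to end.

## Worked example

```r
library(mobikit)

sc <- sim_scenario(n_regions = 2, cells_per_region = 40, n_subscribers = 300,
                   start_date = "2020-02-01", end_date = "2020-02-28",
                   lockdown_date = "2020-02-15", mobility_reduction = 0.3,
                   sampling_regime = "probe_dense", rng_seed = 1)
world <- generate_world(sc)
sim   <- simulate_events(sc, world)

res <- run_pipeline(sim$events, world$cells, world$population,
                    study_config(), out_dir = "out", seed = 1)

res$trends[region_id == "ALL" &
           date %in% as.IDate(c("2020-02-10", "2020-02-28")),
           .(kpi, date, raw_value = round(raw_value, 3),
             pct_change = round(pct_change, 1),
             smoothed = round(smoothed_pct_change, 1))]
#>                     kpi       date raw_value pct_change smoothed
#> 1: collocation_exposure 2020-02-10     3.168       -6.1     -0.3
#> 2: collocation_exposure 2020-02-28     2.204      -34.7    -42.3
#> 3:      n_cells_visited 2020-02-10     3.680       -1.7     -0.1
#> 4:      n_cells_visited 2020-02-28     2.820      -24.6    -24.7
#> 5:        pct_time_home 2020-02-10     0.685        1.6      0.0
#> 6:        pct_time_home 2020-02-28     0.792       17.5     21.8
#> 7:               rog_km 2020-02-10     6.590       -4.5     -0.7
#> 8:               rog_km 2020-02-28     3.055      -55.7    -55.8
```

Before the 15 February lockdown the country-level series sit at their
baseline (smoothed changes ≈ 0). Two weeks after it, time at home is up
~22%, the radius of gyration is down ~56%, and cell diversity and
collocation are down — the signature the pipeline is designed to
surface, here recovered from a scenario whose excursion radius was
shrunk to 0.3 of its pre-lockdown scale.

`run_pipeline()` writes per-subscriber (pseudonymized) tables under
`out/internal/`, and the publishable suppressed aggregates plus a run
manifest under `out/export/`. A command-line wrapper is installed at
`inst/cli/mobikit.R` with `simulate`, `run` and `audit` subcommands;
`audit` exits non-zero if any export violates the k-anonymity contract.

## Documentation

The methods vignette (`vignettes/mobility-insights.Rmd`) documents the
estimators, the allocation and tie-break rules, the synthetic
generator's design and its limits, and the privacy model.
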