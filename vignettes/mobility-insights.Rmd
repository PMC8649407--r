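---
title: "Population mobility insights from network sighting data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population mobility insights from network sighting data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobikit)
library(data.table)
```

## The problem

When a phone exchanges traffic with the network, the operator logs a
timestamp and the serving cell. A table of such sightings —
`(subscriber, timestamp, cell)` — is a coarse, irregularly sampled
trace of where people are. During an epidemic, population-level
summaries of these traces answer questions public-health teams actually
ask: are people staying home, how far do they range, how many gather in
the same place, and how many move between administrative regions?

mobikit turns a pseudonymous sighting table, a cell-site registry and a
region population table into exactly those summaries, under a
privacy-by-design contract: identifiers are re-pseudonymized in
process, and no aggregate is published unless at least *k* (default 50)
distinct subscribers contribute to it.

## The pipeline

1. **Home inference.** For every subscriber and night (22:00–05:00
   local, a window spanning midnight and attributed to the evening's
   date), the cells serving their night events are counted and the top
   3 retained, most-frequent first. Homes are re-estimated nightly
   because residence can genuinely shift during a crisis.
2. **Daily indicators.** Per subscriber-day: the fraction of observed
   time at the ranked home cells; the radius of gyration (RMS
   great-circle distance of the *distinct* cells visited from the
   rank-1 home cell); the number of distinct cells visited; and
   collocation exposure (mean number of other non-home subscribers
   sharing a cell within clock-aligned 60-minute buckets).
3. **Origin–destination matrices.** Events are mapped to regions,
   consecutive same-region runs collapsed, and each ordered pair of
   distinct adjacent regions counted once per subscriber-day: the
   matrix estimates people moving, not trips. Counts are scaled to
   population with a per-region multiplier, `population /
   resident subscribers`, where residency comes from the *previous*
   night's rank-1 home.
4. **Suppression and trends.** Every aggregate below *k* contributors
   is nulled and flagged. Surviving series are expressed as percent
   change from a baseline window (by default the series' first seven
   days, standing in for a pre-crisis reference week) and smoothed with
   a trailing 7-day moving average.

## Modelling choices worth knowing about

**Dwell time from point events.** Sightings are instants, so "time at
home" requires an allocation rule. Each inter-event gap is split at its
midpoint between the two bounding cells; the first and last events of a
day absorb time only inward. This conserves time exactly (per-cell
dwell sums to the first-to-last span) and extrapolates nothing beyond
what was observed. A day with a single sighting has zero span; its
home-time fraction is defined as 1 if the sighting is at a home cell,
else 0, and the row is flagged degenerate. An alternative
`dwell_mode = "counts"` allocates by event-count ratio for sensitivity
checks.

**Radius of gyration.** Distinct cells are unweighted — a cell visited
ten times counts once. That makes the indicator a property of the day's
*set* of places, robust to sampling rate, at the cost of weighting rare
far excursions as heavily as routine ones. Distances use the haversine
formula on a sphere of 6371 km; the radius is configurable
(`earth_radius_km`), and any positive value scales distances linearly.

**Collocation.** Buckets are aligned to clock hours; a subscriber seen
at their own ranked home cell is assumed to be at home and excluded.
Subscribers with no home estimate for a date have an empty home set, so
all their sightings qualify. The country-level series averages
per-subscriber exposures; the per-(cell, bucket) cohort table is also
returned for other aggregations.

**Why the origin multiplier.** A flow A→B is scaled by region A's
multiplier: the extrapolation is anchored where the movers were
resident the previous night, which is also the region whose market
share the multiplier measures.

**Night attribution.** Events between midnight and 05:00 belong to the
previous date's night — one sleep period, one night. Day-D indicators
use the home inferred for night D; OD scaling for day D uses night
D−1. Timestamps are treated as local civil time throughout; no
timezone or DST arithmetic is applied.

**Ties and determinism.** Equal night-cell counts are broken by
lexicographically ascending cell id; event order is totalized by
`(timestamp, subscriber, cell)`. Identical inputs, configuration and
seed reproduce byte-identical output directories.

## The synthetic generator

No public sighting data exists at this granularity, so the package
ships a generator with known ground truth. Its defaults are the
reference study design used throughout the tests: 2000 subscribers
observed for four weeks from 1 February 2020 over four 30-km regions
with urban-grade cell density (150 cells per region, ~2.5 km spacing),
and a lockdown at the start of day 15.

Movement is trip-based. Each subscriber has a fixed true home cell;
each active day draws a small Poisson number of excursion destinations
from an exponential distance-decay kernel (scale 8 km) around home,
snapped to the nearest cell. Day events are served by home (probability
0.35) or a uniformly chosen destination; night events by home
(probability 0.9) or one of its three nearest same-region neighbours,
emulating tower load-balancing. From the lockdown date the kernel scale
is multiplied by `mobility_reduction` (default 0.3). Three sampling
regimes reproduce the operator-data taxonomy: sparse active events
(8/day), dense passive signalling (5×), and an app-like consented
subset (30% of the panel).

The recorded ground truth is the RMS of the *continuous* destination
displacements, whose post/pre ratio equals the configured reduction in
expectation — so the generator's truth recovers the 0.3 factor to
within sampling noise, and the pipeline's radius-of-gyration trend can
be compared against it. On the reference scenario the end-to-end
recovery error is about 8 percentage points, dominated by two honest
gaps between the indicator and the truth: cell snapping puts a floor of
roughly half the inter-site spacing under small excursions, and night
hand-off cells enter the visited set without being excursions.

What the generator does **not** emulate: road networks and commuting
structure, heterogeneous per-subscriber activity rates, daytime
population mixing between homes (destinations are private to a
subscriber-day, so collocation cohorts arise only from shared cells),
device churn, and coverage gaps. Passing tests therefore demonstrate
the estimators' correctness and the pipeline's contracts, not
calibration to any real country.

## Problem sizes and runtime choices

The test suite exercises the estimators against brute-force oracles on
fixtures of up to 200 events, home recovery on 200 subscribers × 7
nights (~12 night events per night), and the full reference scenario
(~2.2 million events), which simulates in ~20 s and runs through the
pipeline in ~10 s on one core. Nearest-cell snapping is chunked so the
candidate distance matrix stays under a few hundred MB.

## Known limitations

* Daily homes are noisy for lightly sampled subscribers; subscriber-
  nights without night events carry no home, and every home-dependent
  indicator is missing (never zero) for those days.
* Sparse rural grids widen cells and flatten the radius of gyration;
  the generator's `rural_regions` option reproduces the geometry but
  not the behavioural differences.
* The k-anonymity rule suppresses exactly the thinly populated areas
  whose mobility one might most want to watch; that is the intended
  privacy/utility trade-off, not a defect.
* Percent-change trends require an honest baseline window; if the
  series starts mid-crisis, `baseline_window` must be set explicitly.
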