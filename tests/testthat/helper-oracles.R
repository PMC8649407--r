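# Independent brute-force oracles, deliberately written in the plainest
# possible style and kept free of any package internals.

# Spherical law of cosines distance, an independent geodesic formula.
law_of_cosines_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  rad <- pi / 180
  cosang <- sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  radius_km * acos(pmin(1, pmax(-1, cosang)))
}

# Midpoint dwell allocation for one subscriber-day, event by event.
oracle_dwell <- function(times, cells) {
  ord <- order(times)
  times <- as.numeric(times)[ord]
  cells <- cells[ord]
  n <- length(times)
  dwell <- setNames(rep(0, length(unique(cells))), unique(cells))
  if (n >= 2) {
    for (i in seq_len(n)) {
      left <- if (i > 1) (times[i] - times[i - 1]) / 2 else 0
      right <- if (i < n) (times[i + 1] - times[i]) / 2 else 0
      dwell[cells[i]] <- dwell[cells[i]] + left + right
    }
  }
  list(dwell = dwell, t_total = if (n >= 2) times[n] - times[1] else 0)
}

# RMS distance of distinct cells from a home cell.
oracle_rog <- function(day_cells, home, registry, radius_km = 6371) {
  cells <- unique(day_cells)
  d <- numeric(length(cells))
  for (i in seq_along(cells)) {
    a <- registry[registry$cell_id == cells[i], ]
    h <- registry[registry$cell_id == home, ]
    d[i] <- law_of_cosines_km(a$lat, a$lon, h$lat, h$lon, radius_km)
  }
  sqrt(mean(d^2))
}

# Nested-loop collocation cohort counts: for each (date, cell, bucket),
# distinct subscribers present whose home set excludes that cell.
oracle_collocation_counts <- function(events, home_sets, bucket_minutes = 60) {
  ev <- data.frame(
    sub = events$subscriber_id,
    date = as.character(as.Date(events$timestamp, tz = "UTC")),
    bucket = (as.integer(format(events$timestamp, "%H", tz = "UTC")) * 60 +
                as.integer(format(events$timestamp, "%M", tz = "UTC"))) %/%
      bucket_minutes,
    cell = events$cell_id,
    stringsAsFactors = FALSE
  )
  keys <- unique(ev[, c("date", "cell", "bucket")])
  counts <- integer(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    here <- ev[ev$date == keys$date[i] & ev$cell == keys$cell[i] &
                 ev$bucket == keys$bucket[i], ]
    subs <- unique(here$sub)
    ok <- vapply(subs, function(s) {
      hs <- home_sets[[paste(s, keys$date[i], sep = "|")]]
      is.null(hs) || !(keys$cell[i] %in% hs)
    }, logical(1))
    counts[i] <- sum(ok)
  }
  cbind(keys, cohort = counts)
}

# Per-date ordered-pair person tally, subscriber by subscriber.
oracle_od <- function(events, registry) {
  region_of <- setNames(registry$region_id, registry$cell_id)
  ev <- data.frame(
    sub = events$subscriber_id,
    date = as.character(as.Date(events$timestamp, tz = "UTC")),
    t = as.numeric(events$timestamp),
    region = region_of[events$cell_id],
    stringsAsFactors = FALSE
  )
  tally <- list()
  for (key in unique(paste(ev$sub, ev$date, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    rows <- ev[ev$sub == parts[1] & ev$date == parts[2], ]
    regions <- rows$region[order(rows$t)]
    collapsed <- rle(regions)$values
    pairs <- character(0)
    if (length(collapsed) >= 2) {
      for (i in seq_len(length(collapsed) - 1)) {
        pairs <- c(pairs, paste(collapsed[i], collapsed[i + 1], sep = ">"))
      }
    }
    for (p in unique(pairs)) {
      k <- paste(parts[2], p, sep = "|")
      tally[[k]] <- (tally[[k]] %||% 0L) + 1L
    }
  }
  tally
}

# home sets keyed "subscriber|date" from an infer_homes() table
home_sets_of <- function(homes) {
  out <- list()
  for (i in seq_len(nrow(homes))) {
    k <- paste(homes$subscriber_id[i], as.character(homes$date[i]), sep = "|")
    out[[k]] <- c(out[[k]], homes$cell_id[i])
  }
  out
}
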