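Package: mobikit
Title: Mobility Insights from Pseudonymous Mobile-Network Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A privacy-preserving analytics toolkit for population-level
    mobility monitoring from pseudonymous mobile-network sighting events
    (call-detail-record-like tables of subscriber, timestamp and serving
    cell). Implements night-time home-cell inference, four daily behavioral
    indicators (percent time at home, radius of gyration about the home
    cell, distinct cells visited, and collocation exposure), daily
    region-to-region origin-destination matrices with population scaling,
    k-anonymous suppression of every published aggregate, and
    baseline-normalized trend series with moving-average smoothing. A
    bundled synthetic event generator with known ground truth (true homes,
    a lockdown change-point in excursion radius) makes the full pipeline
    testable without access to operator data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
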