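Package: multifission
Title: Deterministic Simulation of Multiple-Fission Cell Cycles in Green Algae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven, deterministic simulation of the multiple-fission
    cell cycle of chlorococcal green algae such as Parachlorella kessleri.
    Models the mean light intensity inside a dense culture with a saturating
    optical-depth (Beer-Lambert) attenuation model, stepwise biomass growth
    with commitment points, the reproductive sequences of four multiple-fission
    patterns (consecutive, clustered, Haematococcus-type and the
    Parachlorella polyploidization pattern), a net-starch reserve sub-model,
    and deuterium-stress retardation. Includes division and doubling-time
    statistics, step and replication-round detectors for log2 time series,
    a generator of noisy synchronized-culture observations, and packaged
    reference tables for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
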