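Package: nitrisip
Title: Single-Cell Stable Isotope Probing Ecophysiology of Marine Nitrifiers
Version: 0.1.0
Authors@R: person("GoM", "Nitrifier Project", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for single-cell stable-isotope-probing (SIP) ecophysiology of
    chemolithoautotrophic nitrifiers: atom-fraction arithmetic and Poisson
    counting-error filters for nanoSIMS ion-count tables, bulk process rates
    from 15N tracer time series with labeling correction, per-cell nitrogen and
    carbon assimilation and growth rates, biovolume-to-carbon allometry and
    Redfield nitrogen quotas, population growth from cell counts, Gibbs free
    energy of catabolic reactions under in situ conditions, catabolic energy
    fluxes and biomass yields per Joule, plus seeded synthetic-data generators
    that emulate the measurement structure for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
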