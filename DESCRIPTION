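Package: ppas
Title: Exposure Estimation with Dye-Doped Passive Air Samplers for Chlorine Gas
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating time-weighted-average (TWA) chlorine gas
    exposure from personal passive air samplers (PPAS) built from
    o-dianisidine-doped polydimethylsiloxane. Implements a two-resistance
    diffusion-reaction uptake model with finite colorimetric capacity, the
    extraction-to-exposure estimation chain (reacted chlorine per sampler
    volume, sampler-derived TWA air concentration, CT dose metrics and
    guideline comparisons), processing of PTR/SRI-MS isotopologue channel
    responses into instantaneous concentration series, a synthetic
    chamber-experiment generator for liquid, spray and gel disinfectant
    scenarios, and inverse machinery for kinetic parameter and capacity
    recovery, linear-phase slopes, and two-phase changepoint detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
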