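Package: granulr
Title: Microsensor Rate Analysis for Spherical Phototrophic Granules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts radial microsensor concentration profiles measured in
    spherical microbial aggregates (photogranules, aerobic granules) into
    per-shell net production and consumption rates by differencing diffusive
    fluxes across concentric spherical shells, and estimates gross
    photosynthesis from light-dark-shift oxygen time series, nitrification and
    denitrification from closed-vial 15N tracer incubations, scalar-irradiance
    attenuation from spectral depth profiles, and volumetric carbon fixation
    from 14C microradiograph summaries. A spherical reaction-diffusion forward
    simulator with zero-order layered kinetics, an anoxic-core front, and
    closed-form reference solutions generates synthetic profiles, dark-shift
    transients, isotope series, and light fields with known ground truth for
    verifying every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
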