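Package: mpdna
Title: Mass Photometry Analysis of Nucleic Acids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule mass photometry
    (interferometric scattering) measurements of DNA. Generates landing-event
    streams and synthetic movie stacks with known ground truth, detects landing
    events by ratiometric differential imaging with amplitude and
    radial-symmetry thresholds, decomposes contrast distributions into sums of
    Gaussian peaks, calibrates contrast against DNA length in base pairs or
    nucleotides, and recovers solution mole fractions by correcting observed
    event counts for length-dependent, diffusion-limited binding rates over a
    finite acquisition window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
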