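Package: interfep
Title: Free Energy Profiles of Reactive Species Across the Vacuum-Water
    Interface by Umbrella Sampling and WHAM
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how plasma-generated reactive oxygen and
    nitrogen species (RONS) partition between the gas phase, the
    vacuum-water interface and bulk water.  Provides a synthetic
    umbrella-sampling engine (parametric one-dimensional interface
    potentials sampled by overdamped Langevin dynamics under harmonic
    restraints), a weighted histogram analysis method (WHAM) solver with
    vacuum referencing, symmetrization and window-level bootstrap errors,
    and landmark analysis of the resulting free energy profiles:
    gas-to-surface and surface-to-liquid free energies, hydration free
    energies, Boltzmann concentration enhancements and Henry's-law
    conversions.  All user-facing functions take and return tidy data
    frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
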