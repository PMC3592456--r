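Package: basefret
Title: Simulation and Global Analysis of FRET Between Nucleobase Analogue
    Probes in Nucleic Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds all-atom 3D nucleic acid geometries from rigid-body
    base-pair and base-pair-step parameters (CEHS construction), places
    internal base-analogue FRET probes (tC-family) with their transition
    dipoles, simulates Forster resonance energy transfer including the
    orientation factor averaged over Boltzmann directional distributions of
    the dipoles, simulates and globally fits time-resolved donor decays
    (TCSPC reconvolution), and reconstructs kinked DNA geometries from
    multi-position FRET data under steric and connectivity constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
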