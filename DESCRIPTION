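Package: paibind
Title: Binding, Folding and Docking Analyses for a Transposase DNA-Recognition Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying how the Sleeping Beauty transposase and its
    PAI DNA-recognition subdomain engage transposon DNA. Provides Hill and
    biphasic dose-response fitting for microscale-thermophoresis titrations,
    two-state pH-folding thermodynamics from circular-dichroism ellipticity,
    reconvolution fitting of biexponential time-resolved fluorescence decays
    with global parameter linking, fluorescence anisotropy and
    intensity-weighted lifetimes, NMR chemical-shift-perturbation profiling
    with active-residue selection, pulsed-field-gradient diffusion analysis,
    and rigid-body protein-DNA docking under a knowledge-based
    distance/orientation potential with pose clustering and interface
    annotation. A synthetic-data module generates every input type with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
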