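Package: phloemanifold
Title: Quantitative Evaluation of High-Pressure Manifold Phloem Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale biophysics of symplasmic phloem unloading. Implements
    Hagen-Poiseuille bulk flow and Fick diffusion through plasmodesmal
    microchannels, the plasmodesma-count feasibility analysis for the
    developing wheat grain, diffusion-versus-bulk-flow dominance over
    microchannel radii, pressure-differential scenario arithmetic
    (fruit-excision flux decomposition, sink depressurisation gains), and a
    steady-state conductance-network formalisation of the high-pressure
    manifold in which relative plasmodesmal conductances set resource
    partitioning between competing sinks. All user-facing functions take and
    return tidy data frames; results carry deviation columns against the
    published reference tables they reproduce.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
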