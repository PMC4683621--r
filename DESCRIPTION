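Package: trapcount
Title: Spectral-Count Classification for Protease Substrate-Trapping AP-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for differential spectral-counting analysis of
    tandem-affinity-purification mass-spectrometry (AP-MS) experiments that
    use a substrate-trapping design: a background control purification, an
    active (wild-type) bait, and a catalytically dead "trap" bait. The
    package reads per-replicate protein evidence tables, applies
    score-threshold and replicate-reproducibility filters, performs
    background subtraction with enrichment-factor rescue, and classifies
    every protein as a shared interactor, trap-specific protein (potential
    substrate), wild-type-preferential protein, background binder, or
    low-evidence identification. It ships a count-model simulator with
    planted ground truth, a deterministic reference fixture encoding the
    published summary tables of a mitochondrial CLPXP substrate-trapping
    study in Podospora anserina, recovery evaluation against planted truth,
    annotation joins, ggplot2 visualisations, and broom-style tidiers.
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
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
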