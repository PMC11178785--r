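Package: pilitrack
Title: Track Statistics and Simulation of Pilus-Driven Twitching Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of archaeal twitching motility from
    single-cell tracking data: per-track displacement, path length,
    persistence (confinement) ratio, all-pairs mean squared displacement
    and its log-log slope (anomalous-diffusion exponent), motility
    classification, pilus-retraction kinetics from pilus-length time
    series, and replicate-aware (SuperPlot) cohort statistics with
    one-way ANOVA and Tukey multiple comparisons on replicate means.
    Includes a mechanistic agent-based simulator of
    pilus-retraction-driven twitching (twitchers, tethered wobblers,
    rollers) with calibrated per-strain phenotype presets, a synthetic
    movie renderer, and a detector/linker so the whole pipeline can be
    exercised end to end against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    yaml,
    tiff,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
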