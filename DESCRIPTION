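Package: gutcount
Title: Quantification of Nuclei, Clones and Markers in 3D Confocal Stacks
Version: 0.1.0
Authors@R: person("gutcount", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for quantifying cells in 3D confocal z-stacks
    of fly tissues (adult midgut, imaginal discs): nuclear segmentation by
    fluorescence threshold with distance-transform watershed separation of
    touching nuclei, per-nucleus volume and intensity measurement, volume-based
    size classification (small progenitor-like vs big enterocyte-like nuclei),
    clone classification from mean green-channel intensity, coverslip-proximal
    depth filtering, tissue-level readouts (cell counts, clone ratios,
    marker-positive cell ratios, positive-volume ratios, mitotic spot counts),
    and group-comparison statistics (one-way ANOVA with Tukey HSD, or
    Kruskal-Wallis with Dunn post hoc). Includes a ground-truthed synthetic
    stack generator so every stage is testable without real data, a minimal
    multi-page TIFF codec, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
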