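Package: skinspace
Title: Binned Spatial Transcriptomic Quantification of Senescence in UV-Stressed Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies senescence and DNA-damage gene signatures in binned
    (Visium-HD-style) spatial transcriptomic data from skin tissue. Provides
    bin-level quality control (mitochondrial-content and count filters), a
    positivity-preserving log normalization, marker-based annotation of
    epidermal layers and dermal fibroblasts, gene-positive-bin counts and
    densities per square millimetre with condition-level pooling and
    cross-section directional consistency, and pairwise Wilcoxon rank-sum
    differential expression with detection-fraction filtering. A seeded
    negative-binomial simulator generates layered synthetic skin datasets in
    the standard 10x file layout so the full pipeline is testable end to end.
    Also includes standalone calculators for comet-assay DNA damage metrics,
    mitochondrial membrane potential, nanoparticle loading efficiency,
    logistic replicative-lifespan fitting, and mitochondrial morphology
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
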