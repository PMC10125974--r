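Package: igemscreen
Title: High-Content MBD Foci Screening and Methylome Integration for
    Epigenetic Toxicity Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies fluorescently labelled methyl-CpG-binding domain
    (MBD) foci in two-channel high-content images of pluripotent stem
    cells, normalises the per-nucleus foci parameters to a vehicle
    control, clusters chemicals into hypo-/hyper-/intermediate DNA
    methylation categories, harmonises toxicology-database activity
    records (GENE-TOX, CCRIS, IARC, Tox21) into per-chemical labels,
    ranks activities by random-forest importance against the imaging
    parameters, and summarises genome-wide methylation (array beta
    values, RRBS tiles) together with targeted panel expression.  A
    synthetic-data generator with known ground truth emulates every
    input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    yaml,
    EBImage,
    randomForest,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
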