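Package: ph4screen
Title: Receptor-Based Pharmacophore Modelling and Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, applying and validating receptor-based 3D
    pharmacophore models for multi-kinase inhibitor discovery. Builds
    common-feature pharmacophores (hydrogen-bond acceptor/donor features with
    projected site points, hydrophobic centroids, excluded volumes) from
    aligned protein-ligand complexes, screens small-molecule conformer
    libraries by feature mapping followed by RMSD-minimising rigid (Kabsch)
    superposition with excluded-volume rejection, and validates models on
    active/decoy test sets with an eight-metric suite (sensitivity,
    specificity, yield of actives, enrichment, accuracy, discrimination
    ratio, F1, Matthews correlation coefficient), model ranking, and integer
    confusion-matrix back-solving from rounded metrics. Includes a synthetic
    data generator that plants geometric matches producing a prescribed
    confusion matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
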