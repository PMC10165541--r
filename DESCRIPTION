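Package: spotscreen
Title: Quantification for Genome-Scale smFISH / Protein-Trap Screens of the
    Drosophila Larval Nervous System
Version: 0.1.0
Authors@R:
    person("Screen", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for single-molecule FISH screens
    with fluorescent protein traps: 3D spot detection and subpixel Gaussian
    localization, separation of single transcripts from nuclear transcription
    foci and background shapes, two-channel spot codetection with optimal
    one-to-one matching, 3D marker-channel segmentation with per-compartment
    transcript counting and ghost-bouton classification, an
    assumption-checked statistical decision tree for condition comparisons,
    majority-vote aggregation of multi-annotator presence calls with
    mRNA/protein discordance classification over a nervous-system compartment
    taxonomy, and a seeded synthetic-data generator producing image stacks
    and annotation tables with complete ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
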