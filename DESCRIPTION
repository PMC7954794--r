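Package: sh3kit
Title: Scoring and Analysis of SH3 Domain-Dependent Protein Interaction Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying how protein context shapes SH3-domain
    interaction specificity. Implements colony-size scoring of
    dihydrofolate-reductase protein-fragment complementation (DHFR-PCA)
    screens with plate-background normalization, quantile-based interaction
    calling and SH3-dependency classification; MATCH-style matrix similarity
    scoring (MSS) of position weight matrices against protein sequences with
    random-peptide and PWM-reassignment permutation nulls; deep mutational
    scanning (DMS) scores from variant count tables with synonymous-variant
    scaling and percentile classification; comparison of interaction-profile
    and sequence-similarity dendrograms by cophenetic correlation with a
    label-permutation test; ortholog domain-position and sequence
    conservation utilities; and endocytic single-particle trajectory metrics.
    Seeded synthetic-data generators emulate every input with known ground
    truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
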