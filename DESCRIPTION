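Package: cellmigrate
Title: Management and Analysis of Wound-Healing and Exclusion-Zone Cell
    Migration Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scriptable analysis of collective cell migration data from
    wound-healing and cell exclusion zone assays. Models multi-well plate
    experiments with annotated biological conditions and technical
    replicates, imports per-well tab-separated time/area trajectories,
    exchanges complete experiments as validated XML, normalizes areas
    relative to time zero, performs two-stage quality control (kernel
    density detection of against-trend area jumps and Euclidean-distance
    screening of technical replicates), estimates migration velocity by
    linear regression of normalized area on time, compares conditions
    pairwise with the Mann-Whitney U test under Bonferroni or
    Benjamini-Hochberg correction, and renders deterministic analysis
    reports. Includes a synthetic-experiment generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
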