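Package: MSAcons
Title: Conservation and Variability Profiling of Protein Alignments with
    Structural Compartment Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores per-column conservation and variability of protein
    multiple sequence alignments with seven metrics (Shannon, Schneider,
    Kabat, Landgraf, cumulative relative entropy, real-valued Evolutionary
    Trace and a min-max normalized dominant-frequency E-score), supports
    Henikoff position-based sequence weighting, substitution-derived
    pseudo-counts and reduced-alphabet grouping, validates alignments via
    consensus similarity and pairwise-distance outlier screening, maps
    dispersed structure residues (tunnels, gates, binding sites) onto
    alignment columns with PDB REMARK 465 missing-residue correction, and
    compares compartment variability against the rest of the protein with
    the two-sample Kolmogorov-Smirnov test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'alignment-io.R'
    'profile.R'
    'weighting.R'
    'scores.R'
    'consensus.R'
    'upgma.R'
    'structure-map.R'
    'compare-stats.R'
    'fixtures.R'
    'plots.R'
    'cli.R'
RoxygenNote: 7.3.3
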