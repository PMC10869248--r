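Package: varmap3d
Title: Missense Variant Pathogenicity Concordance and Protein Structure Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking in-silico missense pathogenicity
    predictors against functional-assay truth and for projecting per-variant
    pathogenicity onto predicted protein structures. Parses ANNOVAR-style
    variant tables, harmonizes categorical predictor vocabularies, normalizes
    quantitative scores, tabulates tool-vs-assay concordance with a three-way
    triage of inter-tool agreement, computes false positive rates on
    experimentally benign variants, paints per-residue scores into the
    B-factor column of PDB files, superposes structure models by the Kabsch
    algorithm with iterative outlier rejection, and tests for 3D clustering
    of pathogenic residues by label permutation. Ships the IRF6 case-study
    tables as plain-text fixtures together with generators for synthetic
    variant panels and toy structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
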