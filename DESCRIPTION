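Package: betatraj
Title: Temporal Stratification of Gene Trajectories in Pancreatic
    Beta-Cell Differentiation Time Courses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies genes from stem-cell-to-beta-cell differentiation
    time courses (hESC and hiPSC models sampled at D0, D13, D20 and D35)
    into eight trajectory categories from per-timepoint fold changes
    against the D0 baseline and the change-in-fold-change ratio between
    the endocrine-progenitor (D20) and beta-like-cell (D35) stages, then
    intersects category assignments across cell models. Includes
    per-contrast differential expression (mean-ratio fold change plus a
    Welch test on log2-transformed abundances, or pass-through of
    externally computed tables), transcription-factor overlay against a
    curated registry, hypergeometric gene-set over-representation with
    Benjamini-Hochberg FDR control, heatmap gene ordering, the
    three-hairpin knockdown intersection filter, the 2^-ddCt qPCR
    utility, and a synthetic-data generator that plants known trajectory
    classes so every stage has a ground-truth oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pheatmap
Config/testthat/edition: 3
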