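Package: ribopp
Title: Polyproline-Motif Translation Efficiency and Metabolite Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for linking polyproline (PP) motif content of proteins to
    translation-efficiency (TE) changes measured by paired RNA-seq and
    ribosome-profiling count matrices, and for identifying monotone
    metabolite trajectories shared across ordered cohorts. Includes a
    seeded synthetic-data generator (negative-binomial counts with
    motif-dependent translational repression, planted trajectory panels and
    gene sets), a protein PP/PPG/PPP motif scanner, per-replicate TE
    computation with Welch-test classification of differential TE,
    contingency/rank/hypergeometric enrichment statistics, fuzzy c-means
    trajectory clustering with elbow-based cluster-number selection, PCoA
    and PERMANOVA, closed-form wet-lab assay metrics (migration rate,
    invasion area, IHC composite score, 2^-ddCt fold change), and a
    deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    fgsea,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    e1071,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
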