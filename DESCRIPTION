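Package: limbphylo
Title: Comparative Transcriptomics of Limb Development Across Species
Version: 0.1.0
Authors@R: person("limbphylo", "developers", role = c("aut", "cre"),
    email = "limbphylo@example.org")
Description: Tools for comparing bulk expression profiles of developing
    fore- and hind limbs across species: FPKM quantification and
    median-of-ratios between-sample normalization, construction of a
    cross-species ortholog core set from tabular homology hits,
    phylostratigraphic gene-age assignment on a species tree,
    cross-species expression conservation statistics (mean pairwise
    Spearman with subsampling confidence intervals), multiscale-bootstrap
    cluster significance (bootstrap probabilities and approximately
    unbiased p-values), transcriptome age index profiles with a
    permutation test against a gamma-fitted null, and fore/hind limb
    divergence-set analysis. A seeded synthetic-data generator emulates a
    four-species, two-limb, three-stage limb development design so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
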