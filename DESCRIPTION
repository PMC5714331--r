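Package: miRpanel
Title: Global-Mean Normalization and Group Contrasts for Circulating miRNA RT-qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plasma circulating microRNA RT-qPCR panels in
    glucose-tolerance progression cohorts. Implements assay-level quality control
    (melting, amplification efficiency, negative-control margin), hemolysis and
    spike-in checks, global-mean normalization to normalized relative quantities
    (NRQ) with a model-based reference-stability score justifying the normalizer,
    per-group co-regulation diagnostics on rank correlations, a group-contrast
    lattice with significance categories and hierarchical clustering of group
    profiles, clinical summary statistics (one-way ANOVA reconstructed from
    summary data, exact contingency tests, HOMA-IR), and a seeded synthetic
    cohort generator that emulates the data structure of a 179-assay, 27-sample
    pre-diabetes progression panel for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
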