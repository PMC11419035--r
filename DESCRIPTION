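Package: lcrep
Title: Immunoglobulin Light-Chain Repertoire Analysis for AL Amyloidosis
Version: 0.1.0
Authors@R:
    person("lcrep", "Developers", email = "lcrep-devel@example.org", role = c("aut", "cre"))
Description: Analysis of monoclonal immunoglobulin light-chain variable-region
    repertoires in plasma cell dyscrasias. Assigns rearranged kappa/lambda
    sequences to their germline V and J precursor genes, classifies V-J
    coverage, collapses proximal/distal IGKV paralogs and the IGLJ2/IGLJ3
    ambiguity, tabulates paralog-collapsed gene usage per cohort and tests
    per-gene enrichment with odds ratios and Benjamini-Hochberg FDR, computes a
    length-normalised somatic mutation-frequency statistic, scores variable
    domains for isoelectric point (EMBOSS pKa set) and Kyte-Doolittle
    hydropathy, and evaluates external amyloidogenicity predictions with
    sensitivity/specificity/accuracy. Includes a seeded synthetic-repertoire
    generator with ground truth for end-to-end validation, and a pipeline
    driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
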