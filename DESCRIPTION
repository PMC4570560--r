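Package: silacsites
Title: Quantitative Triple-SILAC Phosphoproteomics: Ratio Significance,
    Kinase-Target Enrichment and Functional Context
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for anchored two-set triple-SILAC
    phosphoproteomic experiments. Computes normalized log2 phosphosite ratios,
    including cross-set ratios chained through a shared reference channel;
    calls differentially phosphorylated sites with the intensity-binned
    asymmetric outlier statistics Significance A and Significance B; classifies
    serum-withdrawal responses into correlated and anti-correlated groups;
    scores residue-level kinase target sets by pre-ranked Kolmogorov-Smirnov
    enrichment with permutation-normalized enrichment scores and permutation
    false discovery rates; and summarizes functional context by hypergeometric
    annotation over-representation and high-confidence interaction-network
    neighborhoods. Ships a fully deterministic synthetic-data generator with
    planted ground truth for calibration and power studies, and a pipeline
    driver that runs the whole analysis from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
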