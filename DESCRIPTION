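Package: mirhub
Title: Identification of Regulatory Hub miRNAs from Paired mRNA/miRNA
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Mirhub", "Developers", email = "mirhub@example.org",
           role = c("aut", "cre"))
Description: Tools to identify candidate "regulatory hub" microRNAs from
    paired gene-expression and small-RNA sequencing experiments. Implements
    seed-based miRNA target prediction over 3'UTR sequences (TargetScan-style
    6mer/7mer-A1/7mer-m8/8mer site taxonomy), a Monte Carlo target-set
    enrichment test with 3'UTR-length normalization and add-one empirical
    p-values, quantile normalization and t-test/FDR/fold-change gating of
    expression matrices, count filtering and library-size normalization of
    miRNA read-count tables, TRANSFAC-format position weight matrix parsing
    with exact score p-value calibration, promoter extraction around
    transcription start sites, and PWM scanning for upstream transcription
    factor binding sites. Includes a synthetic-data generator with planted
    ground truth for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
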