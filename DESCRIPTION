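Package: methager
Title: Ageing Methylome Analysis from Per-CpG Bisulfite Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome bisulfite sequencing studies of
    ageing in insects with sparse methylomes. Starting from Bismark-style
    per-CpG count files, the package merges strands, filters and normalises
    coverage, estimates the bisulfite non-conversion error from an unmethylated
    lambda spike-in, calls methylated CpGs by a binomial test against that
    error rate, detects differentially methylated positions by per-CpG
    logistic-regression likelihood-ratio tests, screens for variably
    methylated positions by the Breusch-Pagan heteroscedasticity test with
    Holm correction, computes per-sample methylome Shannon entropy and fits a
    beta-regression entropy ageing model, trains an elastic-net epigenetic
    clock with seeded cross-validation, and runs hypergeometric GO-term
    enrichment against configurable methylated-gene backgrounds. A
    beta-binomial methylome simulator generates study-structured synthetic
    libraries with ground truth so every stage is testable without the
    original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    lmtest,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
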