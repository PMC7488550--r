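Package: ptwas
Title: Probabilistic Transcriptome-Wide Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Causal inference for transcriptome-wide association studies
    (TWAS) using probabilistic eQTL annotations. Implements composite
    instrumental variables built by Bayesian model averaging over
    fine-mapped eQTL association models, gene-trait scan tests on
    individual-level data or GWAS summary statistics, signal-cluster-level
    causal effect estimation with inverse-variance-weighted meta-analysis,
    Cochran's Q / I-squared diagnostics of the exclusion-restriction
    assumption, Cauchy-combination (ACAT) multi-tissue testing with
    Storey q-value FDR control, a lightweight Bayesian multi-SNP
    fine-mapper, and a simulation framework for power, calibration and
    estimation-accuracy experiments under a two-sample design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
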