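Package: mrtriage
Title: Mendelian Randomization and Glycemic-Burden Triage of Lipid Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-sample summary-data Mendelian randomization and multi-trait
    triage of LDL-cholesterol loci as drug-target candidates. Reads GWAS
    summary-statistic tables in configurable column dialects, harmonizes
    effects to the exposure-raising allele, performs P-value-prioritized LD
    clumping and pruning, estimates causal effects via per-SNP Wald ratios
    with delta-method standard errors pooled by fixed-effects meta-analysis,
    builds a multi-trait glycemic burden composite with Kendall-tau trait
    screening and genomic-control diagnostics, and classifies loci as
    glycemia-neutral drug-target candidates or glycemic liabilities using
    directional concordance and Fisher exact enrichment statistics. Includes
    a synthetic summary-statistics generator with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
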