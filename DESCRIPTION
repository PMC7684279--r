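Package: transprs
Title: Transethnic Polygenic Risk Score Pipeline with Liability-Threshold Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for transethnic polygenic risk score (PRS)
    analysis from genome-wide association study (GWAS) summary statistics and
    target genotype dosages: summary-statistic and dosage file input/output,
    variant quality control (strand-ambiguity, Hardy-Weinberg exact test,
    minor allele frequency and imputation-quality filters), effect-allele
    harmonization, sliding-window linkage-disequilibrium pruning, p-value
    threshold scoring across nested cutoffs, and the downstream statistics
    (adjusted R-squared and Nagelkerke pseudo-R-squared association scans,
    three-group trend and interaction tests, Kaplan-Meier/log-rank survival
    comparison, chi-squared and ANOVA summaries). A companion synthetic-data
    generator simulates LD-blocked genotypes, marginal discovery summary
    statistics, and a liability-threshold target cohort of cases, unaffected
    first-degree relatives and controls with a genetically correlated smoking
    trait, so the whole pipeline can be exercised and calibrated without
    access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    survival,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
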