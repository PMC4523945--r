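Package: snpmeta
Title: Genotype-Count Meta-Analysis for SNP Case-Control Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of biallelic SNP case-control association
    studies from per-study genotype counts. Builds the five classical genetic
    model contrasts (homozygote, heterozygote, dominant, recessive, allele),
    tests Hardy-Weinberg equilibrium in controls, pools odds ratios with the
    Mantel-Haenszel fixed-effect and DerSimonian-Laird random-effects methods
    with Cochran Q / I-squared driven model selection, and provides subgroup
    stratification, leave-one-out sensitivity analysis, and funnel-plot /
    Egger-regression publication-bias diagnostics. Bundles the published
    genotype counts for three TOX3 breast-cancer susceptibility SNPs
    (rs3803662, rs12443621, rs8051542) as worked datasets, and includes a
    calibrated generator of synthetic study panels for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
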