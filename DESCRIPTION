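Package: pafcc
Title: Population Attributable Fractions for Prothrombotic Genotypes in
    Case-Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of individual and cumulative population attributable
    fractions (PAF) of venous thromboembolism for carrier-coded prothrombotic
    genotypes in a case-cohort design. Implements carrier/noncarrier genotype
    coding, a Prentice-weighted Cox proportional hazards fitter with age as the
    time scale and delayed entry, Levin's PAF formula, cumulative multi-SNP PAF
    curves with age-band stratification, bias-corrected percentile bootstrap
    confidence intervals, and a Hardy-Weinberg cohort simulator with Gompertz
    baseline hazards for validating the estimators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
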