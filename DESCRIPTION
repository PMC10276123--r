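Package: kinmr
Title: Lifecourse Mendelian Randomization with Family-History-Proxied Outcomes
Version: 0.1.0
Authors@R: person("kinmr", "maintainers", email = "kinmr@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization when disease
    outcomes are proxied by reported illness in first-degree relatives
    (GWAS-by-proxy / kin-cohort designs). Provides GWAS summary-statistics
    input/output and effect-allele harmonization, greedy LD clumping for
    instrument selection, univariable estimators (inverse-variance weighted,
    MR-Egger, weighted median) with Benjamini-Hochberg FDR gating,
    multivariable MR for lifecourse total/direct/indirect effect
    decomposition and three-exposure mediation, de-attenuation of
    proxy-outcome estimates by the genotypic sharing coefficient, and a
    family-trio simulator with Mendelian transmission and a
    liability-threshold disease model that emulates parental illness
    reports coded 0/1/2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
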