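Package: pedmut
Title: Pedigree-Based Germline Mutation Rate and Sex-Bias Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating per-generation germline mutation rates and
    sex-specific mutation biases from sequenced pedigrees. Implements trio
    de novo mutation (DNM) calling from multi-sample genotype data with a
    seven-filter candidate screen, callability-corrected mutation-rate
    estimation, read-tracing parent-of-origin phasing, identity-link Poisson
    regressions of mutation counts on parental age, mutation-spectrum and
    transmission statistics, and long-term male-to-female substitution-bias
    estimation from X-versus-autosome branch lengths. A synthetic pedigree
    cohort simulator with a complete truth set makes every stage testable
    without access to raw sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
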