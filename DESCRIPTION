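Package: patgwas
Title: Pleiotropic Association Testing for Multi-Trait GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint association testing across multiple traits from GWAS
    summary statistics. Implements a multivariate-normal likelihood-ratio
    omnibus test (PAT) whose alternative covariance decomposes into
    environmental and genetic components, with critical values and p-values
    calibrated by importance-sampled null simulation for accurate extreme
    tails. Omnibus hits are interpreted per trait with m-values (posterior
    probabilities over effect configurations) after rescaling the genetic
    covariance by an estimated causal-variant count. Includes summary-
    statistic harmonization and QC, a synthetic z-score simulator for power
    and calibration experiments, and replication analytics (m-value
    clumping, one-sided directional tests, sign-concordance binomial tests,
    and power deciles).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, data.table
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
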