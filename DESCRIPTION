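Package: hybridpanel
Title: Diagnostic SNP Panels and Hybrid Generation Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building species-diagnostic SNP panels and for
    classifying hybrid and backcrossed individuals between two deeply
    diverged populations. Provides synthetic genotype baselines under
    Hardy-Weinberg equilibrium, an in-silico Mendelian crossing engine
    (F1 hybrids and iterated reciprocal backcrosses), per-locus panel
    diagnosticity statistics with Agresti-Coull minor-allele-frequency
    bounds, a binomial maximum-likelihood classifier of hybrid generation
    from heterozygous-marker counts, likelihood-based genetic assignment
    (empirical conditional maximum likelihood and the Rannala-Mountain
    Bayesian method), dual-ancestry detection for hybrid-by-hybrid
    offspring, and candidate-SNP selection from pooled-sequencing allele
    counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
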