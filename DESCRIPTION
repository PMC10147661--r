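Package: grnmap
Title: Genotype-Phenotype Maps of CRISPRi Gene Regulatory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic ordinary differential equation models of three-node
    synthetic gene regulatory networks built from CRISPR interference parts
    (sgRNAs of graded strength, constitutive promoters, arabinose induction),
    together with the machinery to study their genotype-phenotype map:
    exhaustive enumeration of the genotype space, stripe and oscillation
    phenotype classification, genotype-network statistics (robustness,
    evolvability, transition frequencies, random mutational walks, epistasis),
    heteroscedastic measurement-error models, global parameter estimation
    against microplate fluorescence time series, and a synthetic-data
    generator that emulates the experimental design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    generics,
    dplyr,
    ggplot2,
    igraph,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
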