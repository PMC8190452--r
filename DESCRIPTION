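Package: casteage
Title: Individual-Based Simulation of Caste-Specific Ageing in Social Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based evolutionary simulation of ageing in monogynous,
    haplodiploid social insect colonies. A fixed-size population of colonies
    evolves caste- and age-specific intrinsic survival probabilities and
    fecundities under biased, correlated (antagonistically pleiotropic)
    mutations, selection and drift. Five mutational-architecture scenarios
    encode within- and between-caste antagonistic effects as block
    partial-correlation matrices that are converted to mutational covariance
    matrices; extrinsic mortality acts only on foraging individuals. The
    package provides the scenario matrices and mutation sampler, diploid
    gene-regulatory-network genomes with logistic trait expression, per-colony
    resource and offspring dynamics, the population stepper (reproduction,
    survival, colony collapse, egg-weighted requeening, mating), life-expectancy
    and lifetime-fecundity summaries with proportion transforms, and a
    replicated scenario-grid runner with tidy outputs and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
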