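Package: singletonMaps
Title: Geographic Mapping of Genetic Diversity from the Empirical
    Distribution of Singletons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-level estimation of genetic diversity from the
    empirical distribution of singletons (the share of a sample's
    uniquely represented derived alleles carried by each chromosome),
    together with the coalescent theory that predicts it from external
    branch lengths. Includes Kingman and two-population split-model
    coalescent simulators with infinite-sites mutation, a spatially
    explicit demic range-expansion simulator (forward logistic deme
    demography, conditioned backward coalescent), ordinary kriging of
    diversity surfaces, and approximate Bayesian computation with
    regression adjustment to infer the geographic origin of a range
    expansion from spatially clustered singleton histograms.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    ape,
    nnet,
    MASS,
    jsonlite,
    vcfR,
    geosphere,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
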