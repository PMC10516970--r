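Package: vaporqsip
Title: Taxon-Specific Microbial Growth from 18O Water-Vapor qSIP Density Gradients
Version: 0.1.0
Authors@R:
    person("Soil Microbial Ecology", "Tools Contributors",
           email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates taxon-specific 18O enrichment and relative growth
    rates of soil bacteria and archaea from water-vapor equilibration
    quantitative stable isotope probing (vapor-qSIP) experiments. Takes
    fraction-resolved 16S amplicon counts, droplet-digital-PCR totals and
    CsCl buoyant densities; computes weighted average densities, per-taxon
    excess atom fraction 18O and per-day relative growth rates; summarises
    growing-community size, richness, proportional 18O assimilation and
    treatment overlap; and provides the compositional statistics layer
    (centered log-ratio transform, PCA, two-way permutation PERMANOVA,
    two-way ANOVA, Welch t-tests, Benjamini-Hochberg correction). Includes
    dosing calculations and exponential-curve fitting for 18O water-vapor
    equilibration, and a synthetic gradient-data generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    vegan,
    car,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
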