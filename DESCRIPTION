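Package: hedgescape
Title: Urban Landscape Genetics: SNP Filtering, Resistance Surfaces,
    Connectivity and MLPE Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for individual-based landscape genetics in fragmented
    urban environments, motivated by studies of Western European hedgehogs
    (Erinaceus europaeus) in cities. Implements a post-variant-calling SNP
    filter chain with per-step reporting; population-genetic summaries
    (standardised individual heterozygosity, observed and expected
    heterozygosity, rarefied allelic richness, private alleles,
    Weir-Cockerham Fst with bootstrap confidence intervals,
    Queller-Goodnight relatedness, Evanno delta-K post-processing, Moran's
    I spatial autocorrelation); categorical landcover mosaics converted to
    resistance surfaces under named movement hypotheses; least-cost-path
    and random-walk commute distances on raster graphs with passage maps
    and explicit routes; and maximum-likelihood-population-effects (MLPE)
    mixed models comparing isolation-by-distance against
    isolation-by-resistance by AICc and BIC. A synthetic-data module
    generates landscapes, pedigrees and genotype matrices with known truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
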