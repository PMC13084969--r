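Package: demescope
Title: Deme-Level Conservation Genomics: Heterozygosity, Differentiation and
    Spatial Structure from Joint-Genotyped Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for conservation genomics of small,
    geographically structured populations ("demes") genotyped jointly at
    variant and invariant sites. Implements per-individual autosomal
    heterozygosity with invariant-site denominators, per-deme inbreeding
    coefficients (F_IS), pairwise Weir-Cockerham F_ST with locus bootstrap
    significance, Rousset's a-hat with Mantel isolation-by-distance tests,
    principal component scores, a moment-estimator kinship screen, a
    sex-linkage screen, a RADseq-style genotype and locus filtering cascade,
    and ordinary kriging of individual heterozygosity onto a spatial grid.
    Ships a synthetic-data generator producing VCF and metadata with known
    hierarchical divergence, inbreeding, relatedness and spatial structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    methods,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    geosphere,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
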