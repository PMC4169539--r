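Package: aimsel
Title: Fine-Scale Population Structure and Ancestry-Informative Marker
    Selection for Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects fine-scale population structure in biallelic SNP
    genotype matrices and selects small marker panels that capture it.
    Implements genotype standardization and principal component analysis
    with Tracy-Widom significance of components, tests of concordance
    between genetic and geographic coordinates (Spearman axis
    correlations, best-alignment bearing, Mantel and Procrustes
    permutation tests), pairwise Hudson Fst with a genetic-indistinctness
    threshold, ancestry-informative marker (AIM) ranking by Rosenberg's
    informativeness with LD thinning and leave-one-population-out
    stability, PCA-informative marker (PCAIM) ranking by eigenvalue-
    weighted loadings with positional cluster pruning, and K-nearest-
    neighbour ancestry assignment with a 5-4-3 majority-vote fallback.
    Includes a seeded multi-population genotype simulator
    (Balding-Nichols differentiation, geographic allele-frequency clines,
    selection-like clinal loci, LD blocks, missingness) emulating a
    European-cohort study design, PLINK1 and TSV genotype input/output,
    and a cached end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
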