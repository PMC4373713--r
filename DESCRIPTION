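Package: popdiffr
Title: Population-Differentiation Measures, Simulation Benchmarking, and
    Enrichment Analysis of Drug-Related Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes four per-SNP measures of population differentiation
    (Weir and Cockerham's Fst estimator, the Pearson chi-square test of
    allele-frequency homogeneity, the one-way ANOVA F-test on allele
    dosages, and the nearest-shrunken-centroid standardized-distance sum
    SS_d), benchmarks their sensitivity and specificity under a fully
    specified Hardy-Weinberg multinomial simulation over balanced and
    unbalanced three-population designs, classifies SNPs and genes into
    high- and low-differentiation groups by Wright's Fst categories, and
    tests gene groups for term over-representation with the hypergeometric
    test and Benjamini-Hochberg false-discovery-rate control against
    configurable gene backgrounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
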