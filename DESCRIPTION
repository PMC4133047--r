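Package: admixpulse
Title: Population Structure and Pulse-Admixture Dating from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing population structure and recent admixture
    history from diploid SNP genotype panels. Provides PED/MAP import and
    export with quality-control filtering, dataset merging with strand
    reconciliation and sliding-window LD pruning; recombination-map-defined
    haplotype blocks with EM-estimated haplotype frequencies and Nei
    heterozygosity; waypoint great-circle distances and the serial-founder
    heterozygosity-distance regression; Weir-Cockerham FST matrices with
    classical multidimensional scaling and BIONJ trees with locus-bootstrap
    support; allele-sharing dissimilarities with geographically balanced
    resampling, Procrustes comparison and a permutation test for cluster
    separation; EM estimation of individual ancestry proportions with
    replicate-mode grouping; and moment-based dating of a single admixture
    pulse from the mean and variance of individual ancestry fractions. A
    synthetic-data module generates genotype datasets with known ground truth
    (serial-founder source chains, differentiated colonist sources and
    pulse-admixed hybrid populations) so that every stage can be validated
    against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vegan,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Genetics, Clustering
RoxygenNote: 7.3.3
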