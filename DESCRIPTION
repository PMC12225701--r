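Package: sedacomp
Title: Comparing Metabarcoding and Shotgun Metagenomics of Sedimentary
    Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for side-by-side analysis of the two sequencing arms used
    on sedimentary ancient DNA (sedaDNA) records: the metabarcoding
    post-denoising filter cascade (singleton removal, negative-control floor,
    amplicon length window, rarefaction, cumulative sum scaling, lowest
    common ancestor assignment of amplicon sequence variants) and the
    metagenomic profiling chain (similarity-band filtering, per-read LCA,
    genus aggregation, positional C-to-T damage counting). Includes a
    binomial age-damage model that fits per-taxon deamination amplitude with
    a Wald significance statistic, builds a terrestrial-plant calibrated
    minimum-damage envelope over sample age, and authenticates detections as
    ancient; alpha and beta diversity comparison statistics (richness
    regression, Bray-Curtis and Jaccard dissimilarities, NMDS/PCoA
    ordination, procrustes and Mantel permutation tests); and a seeded
    taphonomic simulator of complete sedaDNA records with known ground truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    vegan,
    withr,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
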