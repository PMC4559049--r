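Package: kindisp
Title: Pedigree-Based Natal Dispersal Estimation from Noninvasive SNP
    Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates individual-based natal dispersal distances in wild
    populations from noninvasively collected, replicated SNP genotypes.
    Provides genotype quality control for fecal-sample panels (replicate
    consolidation, genotyping error and allelic dropout estimation,
    Y/X-chromosome sex calling, mitochondrial haplotype assignment,
    probability of identity), Lynch-Ritland pairwise relatedness with
    locus weighting, likelihood-based parentage assignment with
    genotyping-error models and posterior filtering, median-center home
    range estimation with Mantel isolation-by-distance tests, and
    sex-stratified dispersal summaries with rank-sum testing. Includes a
    truth-known spatial pedigree simulator emulating a noninvasive
    sampling design, so every stage of the pipeline can be validated
    against known parentage and dispersal kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
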