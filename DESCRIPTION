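Package: casvpipe
Title: Multi-Amplicon Microbiome Merging, Similarity Modelling and
    Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis machinery for multi-amplicon gut-microbiome studies
    of wild mammal populations. Merges amplicon sequence variants (ASVs)
    that originate from the same taxon into combined ASVs (cASVs) by
    within-genus co-abundance network clustering; computes Bray-Curtis,
    Jaccard and Aitchison beta-diversity with distance-based intraclass
    correlation (dICC) repeatability and bootstrap standard errors; fits
    Bayesian dyadic multi-membership regressions of microbiome similarity
    on host and environment distances by blocked Gibbs sampling; provides
    a random-forest harness (stratified split, repeated cross-validation,
    permutation importance, partial dependence) for predicting faecal
    immune measures from taxon abundances; and infers sparse microbial
    co-occurrence networks by neighbourhood selection with centrality
    comparison. A synthetic-data module simulates hosts, immune measures,
    latent taxa and multi-amplicon ASV observations with known ground
    truth so every stage can be validated against a recoverable target.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    glmnet,
    ranger,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
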