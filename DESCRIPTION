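Package: ornadiv
Title: Cross-Modal Courtship Ornament Complexity and Correlated Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the complexity of courtship phenotypes across three
    signal modalities (display behavior, plumage color, courtship sound) and
    tests their correlated evolution on a phylogeny. Provides Shannon-entropy
    numbers equivalents (Hill numbers of order 1) with sliding-window maxima
    for behavioral and acoustic event sequences; receptor-noise-limited
    chromatic and achromatic discrimination distances (JNDs, log model) with a
    spatial agglomerative clustering of cone-catch images into perceptually
    distinct color patches; two-step note classification (PCA plus
    hierarchical clustering merged with qualitative note categories);
    phylogenetic generalized least squares under an Ornstein-Uhlenbeck
    correlation structure with maximum-likelihood decay rate; model-compared
    phylogenetic imputation of missing species values; and synthetic-data
    generators with known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
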