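Package: semharmony
Title: Semantic Harmonization of Psychopathology Rating Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonizes items from multiple psychopathology rating scales by
    the meaning of their descriptive texts. Item descriptions are embedded as
    dense vectors (a deterministic offline mock backend is provided alongside
    a pluggable sentence-transformer reference backend), pairwise cosine
    similarity matrices are built at item and scale level, items are
    classified against construct descriptions (e.g. positive versus negative
    formal thought disorder), the cross-scale similarity network is
    sparsified onto a backbone scale to derive semantic clusters, multi-rater
    Fleiss' kappa quantifies expert-machine assignment agreement, and an
    exact binomial co-clustering test checks whether cross-scale clinical
    item correlations fall within the derived semantic clusters. A synthetic
    data generator with known ground truth (themed item texts, noisy expert
    assignments, latent-factor ordinal ratings) makes every pipeline stage
    testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
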