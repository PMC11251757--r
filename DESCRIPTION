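Package: maqsoc
Title: Facial Expressivity and Social Network Attributes in Macaque Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative pipeline linking the facial expressivity of
    dominant male macaques (MaqFACS-coded action-unit event streams) to
    individual and group-level social network attributes. Builds dyadic
    proximity and grooming matrices and the composite Dyadic Sociality
    Index from focal-follow and scan-sampling records, computes weighted
    network metrics (eigenvector and betweenness centrality, strength,
    walktrap modularity, star-normalized centralization), Elo-rating
    dominance attributes (summed winning probability, hierarchy steepness,
    aggression rate), context-nested expressivity measures (action-unit
    rate, duration, Shannon-diversity effective numbers, proportions), and
    a Gaussian GLM likelihood-ratio model grid with k-means clustering of
    action-unit proportions. Includes a synthetic study generator with a
    tunable expressivity-cohesion coupling for calibration and power
    checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    cluster,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
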