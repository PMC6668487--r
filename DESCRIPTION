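Package: psdnet
Title: Structural Connectome Graph Analysis for Post-Stroke Depression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Graph-theoretical analysis of weighted structural brain networks
    (fiber-count connectomes on a 90-region cortical/subcortical parcellation)
    for two-group clinical studies, modelled on post-stroke depression cohorts.
    Provides fiber-count thresholding and max-normalization, weighted global
    and nodal network measures (Onnela clustering, characteristic path length,
    global/local/nodal efficiency, degree, strength, betweenness), small-world
    normalization against degree-preserving randomized surrogates (gamma,
    lambda, sigma), permutation-based group inference with covariate
    residualization and Bonferroni correction, covariate-adjusted Spearman
    correlation of network measures with depression severity, and a seeded
    synthetic cohort generator that emulates the statistical structure such
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
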