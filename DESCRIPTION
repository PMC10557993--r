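Package: synergynet
Title: Higher-Order Synergistic Associations in Sign-Disease Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying higher-order (synergistic) associations among
    binary signs, symptoms and diseases that pairwise association networks miss.
    Provides exact and sampling-based inference for binary Bayesian networks
    with conditional-probability-table edges; discrete information measures
    (entropy, multivariate mutual information, total and dual total correlation,
    O-information, whole-minus-sum synergy); construction of synergistic
    conditional probability tables by whole-minus-sum optimisation, including a
    nine-node reference network with planted synergistic triplets and OR-gate
    diseases; population-level soft ("nudge") interventions with exact log-odds
    effect propagation and individual-level hard (do) interventions with
    counterfactual noise reuse; and a triplet-scanning pipeline that filters
    candidate triangles by low dyadic mutual information, scores them with
    O-information, assigns permutation p-values and controls the false
    discovery rate. Includes generators for survey-style binary datasets with
    planted ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
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
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
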