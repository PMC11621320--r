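Package: curiofish
Title: Curiosity-Driven Artificial Fish and Rule-Based Shoaling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale simulation and analysis of the development of social
    behavior in embodied agents ("artificial fish"). Provides a generative
    single-parameter attraction rule for shoaling (turn toward a randomly
    chosen neighbor a fraction p_s of the time), a planar multi-agent fish
    tank with egocentric ray-cast vision, four intrinsic-motivation reward
    algorithms (intrinsic curiosity module, its random-feature variant,
    random network distillation, and temporal contrastive curiosity) trained
    alongside proximal policy optimization, and the behavioral analysis
    suite used in developmental collective-behavior studies: pairwise
    distance development, focal-frame relative-position maps, configuration
    dependent turning probabilities, attraction-parameter fitting,
    trajectory-randomization significance testing, two-alternative
    forced-choice social preference scoring, and self-segregation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    ggplot2,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
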