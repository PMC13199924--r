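Package: dcekit
Title: Design and Analysis of Discrete Choice Experiments with Utility Balance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing and analysing discrete choice experiments
    (DCEs) for stated-preference surveys, developed around a nurse job-preference
    instrument. Builds D-efficient fractional factorial designs under the
    multinomial logit model with a two-loop constrained search that enforces a
    point-score utility-balance rule and excludes dominant alternatives; checks
    orthogonality and level balance; splits designs into level-balanced blocks;
    constructs a dominant-alternative consistency test; simulates respondent
    panels under configurable choice behaviour; and fits conditional logit
    models by maximum likelihood with odds-scale reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
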