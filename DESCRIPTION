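Package: panmux
Title: Multiplex Social Network Analysis of Chimpanzee Scan-Sampling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for assessing the sociability of captive chimpanzees from
    two-minute scan-sampling observation logs. Computes four mutually exclusive
    dyadic interaction indices (stationary vicinity, affiliative behaviour,
    allogrooming, passive close proximity), builds directed weighted 4-layer
    multiplex networks per social group, and analyses them with interlayer
    edge overlap, Von Neumann graph entropy, quantum Jensen-Shannon divergence,
    structural reducibility, eigenvector centrality and versatility. Dyadic
    linear mixed models test whether the biographical background of sender and
    receiver (origin, infant housing condition, sex) predicts interaction
    indices. A synthetic scan generator with planted dyad-level effects makes
    every stage testable without access to the original sanctuary records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    multcomp,
    car,
    igraph,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
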