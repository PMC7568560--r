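Package: trialnet
Title: Temporal Co-Authorship Network Analysis of Clinical-Trial Publications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the social network of clinical-trial authorship
    from structured publication records: a multiplicative author impact score
    (author role, trial design, normalized citations, update half-life decay),
    cumulative yearly weighted co-authorship networks with density, modularity,
    categorical assortativity, betweenness, PageRank, homophily and
    concentration metrics, per-year primary-subspecialty and career-longevity
    assignment, gender mapping from name-frequency tables, group comparisons
    and gender-trend extrapolation, a coefficient sensitivity analysis, and a
    seeded synthetic corpus generator that emulates the growth, team-size,
    homophily and gender structure of the chemotherapy-trial literature so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
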