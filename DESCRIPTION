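Package: huddlesim
Title: Agent-Based Simulation of Thermoregulatory Huddling in Rodent Litters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates litters of thermotaxic circular agents ("pups") that
    lose heat to the environment, exchange heat through body contact, and
    generate heat internally, in a two-dimensional circular arena. Three model
    variants (endothermic, ectothermic, homeothermotaxic) reproduce the
    self-organised phase transition into huddling at low ambient temperatures
    and the continual "pup flow" between huddle centre and periphery. Provides
    group-level metrics (huddling, pup flow, subgroup counts, mean body
    temperature), ambient-temperature and thermogenesis sweep protocols, and a
    closed-form "super-organism" model of the litter's optimal exposed surface
    area, together with tidy outputs, ggplot2 visualisations and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
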