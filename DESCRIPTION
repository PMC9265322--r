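Package: econetr
Title: Ecological Network Construction from Land-Cover Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates regional ecological networks from categorical
    land-cover rasters and terrain layers. Implements morphological spatial
    pattern analysis (MSPA) to segment habitat into core, islet, edge, bridge,
    branch, loop and perforation classes; graph-theoretic landscape
    connectivity indices (LCP, IIC, PC) with per-patch importance (dPC) and
    dispersal-distance threshold sweeps; AHP-weighted composite resistance
    surfaces; least-cost ecological corridors ranked and tiered by a gravity
    model; hydrologically derived ecological nodes from D8 ridge and valley
    lines; and alpha/beta/gamma/cost-ratio structural evaluation of the
    resulting network. A Markov-chain cellular-automaton module projects land
    cover forward, and a seeded synthetic-landscape generator provides fully
    reproducible demonstration data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
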