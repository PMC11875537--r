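Package: plasmidLV
Title: Multistability of Microbial Communities Exchanging Mobile Genetic
    Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generalized Lotka-Volterra models of competing microbial
    species that exchange mobile genetic elements (plasmids) by
    conjugative horizontal gene transfer.  Provides the coupled ODE
    systems for carrier subpopulation dynamics (growth-rate effects,
    competition modification, epistasis, strong selection, and niche
    structure), compiled right-hand sides integrated with 'deSolve',
    closed-form stability analysis of the two-species Lotka-Volterra
    limit, ensemble-based attractor detection with single-linkage
    clustering, an entropy-based multistability coefficient, phase
    diagrams and transfer-rate scans, and grid metacommunity simulations
    with nearest-neighbour dispersal and Shannon diversity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
NeedsCompilation: yes
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
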