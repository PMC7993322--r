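Package: turbicell
Title: Simulation and Control of Liquid-Handler Turbidostat Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Hardware-free simulation and control toolkit for feedback-run
    microbial cultures on a liquid-handling robot. Implements the turbidostat
    transfer function (growth-constant estimation from consecutive optical
    density reads, first-order filtering, clamped media-replacement commands),
    a stochastic multi-plate closed-loop simulator with measurement and
    mechanical noise, carbon/nitrogen/phosphorus media-condition grids with
    growth and fluorescence landscape summaries, sparse metapopulation liquid
    transfer matrices with diffusion kernels and geographic barriers compiled
    to explicit pipetting steps, and an asynchronous multi-plate deck
    scheduler with step logs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
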