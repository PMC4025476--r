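Package: genevolve
Title: Teaching-Oriented Simulations and Problem Generators for
    Transmission and Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact multilocus Mendelian cross enumeration with autosomal and
    X-linked loci, three-point and two-point testcross mapping (solving for
    gene order, phase and recombination fractions, and generating seeded
    practice problems with answer keys), a forward allele-frequency simulator
    combining genotypic selection, genetic drift and inbreeding,
    Hardy-Weinberg goodness-of-fit and inbreeding-coefficient estimation,
    Breeder's-equation and exponential-growth solvers, a customizable
    four-option terminology quiz engine, and a unified batch problem
    generator with answer checking. Results are tibbles with broom-style
    tidy() and glance() methods and ggplot2 autoplot() methods; a thin
    command-line dispatcher exposes every tool as a subcommand.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
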