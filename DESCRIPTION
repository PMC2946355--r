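Package: salmoncoal
Title: Coalescent Effective Population Size for Semelparous Age-Structured
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Backward-time coalescent theory for semelparous, age-structured
    populations such as Pacific salmon. Builds the single- and two-lineage
    ancestral Markov chains over age classes, performs the two-time-scale
    (fast movement / slow coalescence) decomposition via Kronecker products,
    and computes the coalescent effective population size (CES) in closed
    form. Includes exact backward-time and forward-time Wright-Fisher
    simulators for validation, and extends the theory to fast i.i.d.
    fluctuations in total population size, where the long-term CES follows
    the harmonic mean of yearly sizes and can be compared against the
    classical breeder-count estimators.
License: MIT
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
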