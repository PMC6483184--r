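Package: shiftsim
Title: Agent-Based Simulation of Contact-Induced Language Change Under
    Language Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the spread of a novel linguistic variant in a
    population of first- and second-language speakers during language
    shift.  Agents hold per-speaker usage distributions over variants that
    are updated through pairwise interactions; demographic turnover
    (births of L1 speakers, recruitment of L2 speakers, deaths) drives
    innovation because entering L2 speakers may adopt the novel variant.
    Supports fixed-size, exponentially expanding, and census-driven
    populations, an alternative model in which innovation remains possible
    throughout a multi-year second-language-acquisition window, and a
    model-data comparison pipeline: beta-binomial maximum-likelihood
    estimation of population mean usage from speaker token counts,
    replicate-ensemble confidence intervals, minimum-MSE parameter
    selection, and joint tail probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
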