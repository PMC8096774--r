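Package: crnmut
Title: Simulating Loss- and Gain-of-Function Mutations in Mass-Action
    Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mass-action chemical reaction networks of
    cell signalling and for simulating the effect of cancer-associated
    mutations on their steady states.  Provides exact (integer/rational)
    computation of semi-positive moiety conservation laws and elemental
    species, stoichiometric compatibility classes with the associated
    random-state sampler, projection operators implementing null
    loss-of-function mutations (state projection) and gain-of-function
    mutations (stoichiometric column deletion), stiff ODE integration to
    asymptotic steady states, and a Monte-Carlo protocol that checks
    numerically whether each compatibility class carries a single globally
    attracting steady state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
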