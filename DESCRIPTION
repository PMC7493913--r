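Package: sorbRSM
Title: Response-Surface and Crow-Search Optimization of Biosorption Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for optimizing batch heavy-metal biosorption experiments
    with designed experiments and derivative-free search. Builds three-factor
    Box-Behnken designs, fits the full second-order (quadratic) response
    surface by least squares with a replicate-based lack-of-fit ANOVA and
    standardized-effect (Pareto) ranking, locates the most desirable operating
    point with the Derringer desirability function, cross-checks it with a
    from-scratch crow search algorithm, and fits linearized pseudo-first- and
    pseudo-second-order adsorption kinetics. Ships a 15-run Pb(II) removal
    dataset for the green microalga Chlorella kessleri together with synthetic
    generators that emulate the same data-generating process for testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
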