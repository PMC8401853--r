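Package: bbdopt
Title: Box-Behnken Response-Surface Modelling and Desirability
    Optimization for Nanoparticle Formulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for three-factor Box-Behnken experimental designs and
    their analysis by response-surface methodology: design construction
    with coded/actual level conversion, reduced polynomial model fitting
    by ordinary least squares in coded units (identity or natural-log
    response scale) with lack-of-fit ANOVA against pure error from
    replicated runs, standardized-effect (Pareto) ranking, backward term
    selection, Derringer-Suich multi-response desirability optimization
    over the design cube, checkpoint validation by prediction-error
    percentage, and closed-form formulation metrics (entrapment
    efficiency, cumulative drug release with optional sampling
    correction, wound-closure rate). Includes a synthetic-data generator
    with known ground truth for parameter-recovery studies, and a
    worked nanoparticle formulation dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
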