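Package: nlcqbd
Title: Quality-by-Design Development of Lipid Nanocarrier Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quality-by-design (QbD) computational chain used to
    develop nanostructured lipid carrier (NLC) formulations: two-level
    fractional factorial screening designs and rotatable central composite
    designs with coded/natural-unit conversion; main-effects ANOVA for factor
    screening; response-surface fitting of four nested polynomial model
    classes with model selection and new-observation prediction error;
    multi-response Derringer-Suich desirability optimization by a multi-start
    Nelder-Mead simplex; diffusion-controlled (Crank monolithic-sphere)
    release-kinetics fitting with lag time; and scalar characterization
    formulas (entrapment efficiency, drug loading, crystallinity index,
    Bragg d-spacing, replicate summaries, stability t-tests). Includes seeded
    synthetic-data generators for every pipeline stage and packaged study
    tables for a worked phenobarbital NLC example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
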