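Package: empdcc
Title: Dimensional Toxicology of Elongate Mineral Particles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-particle dimensional metrics for elongate mineral particles
    (thickness, surface area, aerodynamic diameter, criteria-particle score,
    and the Dimensional Coefficient of Carcinogenicity, DCC), population-level
    summaries (criteria fraction, Pearson index, EMPA), classification of
    mineral habit (asbestiform vs. non-asbestiform) from dimensional data by
    a fixed decision boundary, Mahalanobis proximity, or a refitted linear
    margin, mesothelioma-potency prediction models, Monte-Carlo calibration
    of the DCC coefficients, and a seeded synthetic particle-population
    generator for testing every stage without access to raw counting sheets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
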