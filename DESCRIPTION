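Package: odormix
Title: Odor Interaction Modelling for Binary Odorant Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how two odorants combine into a single
    perceived odor intensity. Implements the tangent-intercept (partial
    differential) method borrowed from partial molar volume analysis: panel
    odor-intensity ratings and chemical concentrations are transformed into
    (mixing proportion, averaged odor intensity) coordinates via odor
    activity values, an interaction curve is fitted by least squares, and a
    mixture's odor intensity is predicted from the tangent-line intercepts.
    Includes odor-threshold and odor-activity-value utilities, the
    1-butanol odor intensity referencing scale, classical comparison models
    (vector/U, strongest component, additivity), a seedable synthetic
    sensory-panel generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
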