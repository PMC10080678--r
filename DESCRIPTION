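Package: formosedyn
Title: Dynamic Environmental Forcing of a Formose-Like Reaction Network in a CSTR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how fluctuating environmental inputs shape the
    composition of a model prebiotic (formose-like) reaction network run in a
    continuous stirred-tank reactor (CSTR). The package generates stepwise-
    Gaussian Ca(OH)2 inlet programs balanced to a constant residence time,
    simulates a schematic gated reaction network with a Breslow-cycle core by
    mass-action ODE integration, emulates GC-MS quantification via quadratic
    peak-area calibration, and analyses concentration time traces with
    correlation-distance hierarchical clustering (average linkage), multi-
    timescale windowed-differential Pearson correlation against the input, and
    per-compound distribution comparisons with significance-star annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
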