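Package: artres
Title: Arterial Reservoir and Excess Pressure Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Separates arterial blood pressure waveforms into reservoir and
    excess components. Implements the pressure-plus-flow algorithm (Windkessel
    ordinary differential equation solved by exponential product integration)
    and the pressure-only algorithm (systolic and diastolic rate constants
    with a fitted asymptotic pressure), together with beat segmentation, end-
    systole detection by maximum negative dP/dt, mono-exponential diastolic
    decay fitting, and estimation of total peripheral resistance and arterial
    compliance. Ships validated synthetic-data generators: half-sine aortic
    inflow, two- and three-element Windkessel pressures with a nonzero
    zero-flow asymptote, and a time-delay branching-network reservoir solved
    by the method of steps. A random-effects meta-analysis toolkit
    (DerSimonian-Laird pooling, heterogeneity, prediction intervals, paired
    differences, Egger small-study test, method-of-moments meta-regression,
    subgroup heterogeneity) supports syntheses of zero-flow pressure and mean
    circulatory filling pressure. A command-line interface ties simulation,
    fitting and reporting together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
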