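Package: wholecell
Title: Whole-Cell Patch-Clamp Feature Extraction with Synthetic Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for episodic whole-cell patch-clamp recordings
    of cultured neurons. Detects action potentials in current-clamp sweeps by
    paired dV/dt slope criteria, extracts rheobase, spike threshold (maximal
    curvature), latency, amplitude and full width at half amplitude, estimates
    input resistance, series resistance and capacitance from membrane-test
    pulses, performs ohmic leak subtraction and early/late current extraction
    in voltage clamp, and applies the matching statistical layer (ROUT outlier
    removal, Kruskal-Wallis with Dunn post-hoc tests, Mann-Whitney U,
    repeated-measures two-way ANOVA with Greenhouse-Geisser correction and
    Tukey tests, and origin-constrained one-phase association F-tests). A
    synthetic-cell generator produces cohorts of recordings with exact spike,
    passive-property and current ground truth so every stage of the pipeline
    is verifiable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    minpack.lm,
    tibble
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    ggplot2
Config/testthat/edition: 3
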