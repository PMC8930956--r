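Package: dmwear
Title: Patient-Specific Polyethylene Wear Simulation for Dual-Mobility and
    Conventional Acetabular Cups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulation pipeline comparing polyethylene wear of
    dual-mobility and conventional total hip arthroplasty acetabular
    components.  Generates a synthetic patient cohort with level-walking
    gait cycles (hip joint angles and joint reaction force), solves
    conformal ball-in-socket contact with an elastic-foundation (Winkler)
    model including a yield-stress pressure cap, partitions motion between
    the small and large articulations of dual-mobility cups, accumulates
    per-node linear wear with the Archard law, extrapolates to one million
    walking cycles, and reduces cohort results to paired comparisons
    (paired t, Cohen's d with confidence intervals) and regressions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
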