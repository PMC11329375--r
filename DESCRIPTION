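Package: navloop
Title: Persistent Sodium Current, Glycolytic Acidification and the
    Na_v1.5 Positive-Feedback Loop
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the link between voltage-gated sodium
    channel (Na_v1.5) activity and extracellular acidification in
    carcinoma cells.  Includes a Hodgkin-Huxley-style synthetic
    voltage-clamp generator with P/6 leak records, whole-cell analysis of
    transient and persistent Na+ current (leak subtraction, conservative
    noise correction, current-voltage curves, Boltzmann gating fits,
    window current and channel availability), a stoichiometric model
    chaining persistent Na+ influx through the Na+/K+ ATPase and
    glycolysis to a predicted extracellular acidification rate, a
    fixed-point/ODE simulator of the acidification-current positive
    feedback loop, measurement-calibration pipelines (pH microelectrodes
    with interleaved junction-potential offsets, BCECF two-point
    intracellular pH, SBFI background-subtracted ratios, Seahorse effect
    estimation), and a modified Allred immunohistochemistry scorer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
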