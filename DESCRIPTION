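Package: hfcell
Title: Late Sodium Current and Heart-Failure Remodeling in a Human
    Ventricular Myocyte Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation of the action potential of a single human
    endocardial ventricular myocyte with an explicit late sodium current
    (I_NaL) and a composable description of heart-failure ion-channel
    remodeling.  Provides the compartmental baseline model as a compiled
    ODE right-hand side, voltage-clamp and pacing protocols (steady-state
    pacing, frequency staircase, rate dependence, sodium clamp, early
    afterdepolarization induction), extraction of electrophysiological
    biomarkers (APD90/APD50, triangulation, calcium-transient metrics,
    sodium load, NCX reversal time, EAD detection), and a two-point
    finite-difference sensitivity analysis of those biomarkers to the
    remodeled ionic parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
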