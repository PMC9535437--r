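Package: renautoreg
Title: Renal Autoregulation in a Closed-Loop Gestational Hemodynamic Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter (compartment and connector) simulation of the
    first-trimester maternal circulation with short-term renal autoregulation.
    The closed loop couples a four-chamber time-varying-elastance heart,
    pulmonary and systemic beds, a uterine branch and a lumped single-nephron
    kidney.  Afferent arteriolar resistance is controlled by a myogenic
    response (windowed systolic pressure sensing with asymmetric
    constriction/dilation time constants) and by tubuloglomerular feedback
    (delayed, clamped linear activation on glomerular filtration rate).
    Includes the calibration procedure that regenerates a parameter set
    hitting stated hemodynamic targets, renal perfusion-pressure step and
    autoregulatory-curve protocols, deviation scoring against user-supplied
    reference observations, and one-at-a-time sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
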