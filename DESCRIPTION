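Package: cvfluid
Title: Lumped-Parameter Cardiovascular Response to Hemorrhage and Fluid
    Resuscitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the hemodynamic response of a subject to fluid
    perturbation (hemorrhage, urine loss and fluid infusion) with a low-order
    lumped-parameter model whose outputs are blood volume, hematocrit, heart
    rate, stroke volume, cardiac output and mean arterial pressure.  Provides
    maximum-likelihood calibration of the 22 free model parameters from sparse
    noisy measurement series, a compartment-method virtual-cohort generator
    (mixing and average virtual subjects with resampled baselines), and
    credibility-assessment metrics for predictive-capability evaluation:
    normalized root-mean-square and mean absolute errors, negative
    log-likelihood, physiological and relevance filters, prediction envelopes,
    data coverage and the normalized interval score.  Ships a reference set of
    27 calibrated sheep parameter vectors and synthetic protocol and
    measurement generators so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
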