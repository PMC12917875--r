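Package: mtcinsert
Title: Mid-Trial Dose-Level Insertion for Dual-Agent Dose-Finding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for phase I oncology trials of two agents in combination
    where none of the prespecified dose combinations may be close to the
    target toxicity. Implements a mid-trial dose-insertion rule driven by the
    posterior distribution over monotone maximum-tolerated-contour (MTC)
    partitions of the dose grid, two alternative interval-probability
    insertion rules, and embeds them in two host escalation designs: the
    model-assisted PIPE design (independent beta-binomial posteriors,
    contour-guided weighted randomisation with an overdose rule) and a
    five-parameter two-dimensional Bayesian logistic regression model with
    escalation-with-overdose-control. A simulation engine computes operating
    characteristics (correct/acceptable/subtherapeutic/toxic selection
    proportions, accuracy and utility indices, patient exposure) on built-in
    or user-supplied toxicity scenarios, and a case-study replay reruns both
    designs on a published neratinib/temsirolimus trial.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
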