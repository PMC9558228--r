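Package: rso2entropy
Title: Sample Entropy of Intraoperative Cerebral Oximetry and Postoperative
    Cognitive Improvement
Version: 0.1.0
Authors@R:
    person("rso2entropy", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking the sample entropy (SampEn) of
    intraoperative cerebral near-infrared spectroscopy (NIRS) oximetry
    (rSO2) time series to postoperative cognitive improvement (POCI) after
    carotid endarterectomy. Reads and validates 2-second rSO2 traces with a
    pre-induction baseline window; computes baseline, summary and
    desaturation-burden metrics (duration and area below fractions of
    baseline); estimates SampEn(m, r, N) over a grid of tolerance
    coefficients with an exact O(N^2) template-matching core; screens
    individual series for nonlinear dynamics with amplitude-adjusted
    Fourier-transform (AAFT) surrogate-data rank tests; labels POCI from
    education-adjusted Montreal Cognitive Assessment (MoCA) scores; and
    provides the diagnostic-accuracy statistics layer (chi-square /
    Yates / Fisher policy for 2x2 tables, pooled and Welch t, Mann-Whitney
    z, univariate and backward likelihood-ratio logistic regression, ROC
    AUC with DeLong and Hanley-McNeil intervals, and Hanley-McNeil AUC
    power). A calibrated synthetic-cohort generator emulates the study
    cohort so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
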