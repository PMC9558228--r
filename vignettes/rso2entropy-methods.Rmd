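---
title: "Methods: sample entropy of intraoperative cerebral oximetry and POCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample entropy of intraoperative cerebral oximetry and POCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Carotid endarterectomy (CEA) can improve cognition — postoperative
cognitive improvement (POCI), operationalised as a gain of at least three
points on the education-adjusted Montreal Cognitive Assessment (MoCA)
between the preoperative assessment and postoperative day 3–4. Whether
intraoperative cerebral NIRS oximetry (rSO₂, sampled every 2 s on the
affected side) carries predictive information about POCI is the scientific
question this package operationalises. Conventional summaries — means,
minima, time and area below fractions of the pre-induction baseline —
discard the signal's temporal structure; the package therefore centres on
**sample entropy** (SampEn), a nonlinear regularity measure, as the
candidate predictor, and wraps it in the complete diagnostic-accuracy
statistics layer needed to evaluate it on a cohort.

Because no patient-level data are publicly available, the package ships a
first-class synthetic-cohort generator whose defaults encode the cohort
structure a study of this design reports, so that every pipeline stage is
exercised end-to-end by tests.

## Sample entropy

For a series $u(1),\dots,u(N)$, embedding length $m$ and tolerance $r$,
templates $x_m(i) = (u(i),\dots,u(i+m-1))$ are compared in the Chebyshev
metric $d[x(i),x(j)] = \max_k |u(i+k-1)-u(j+k-1)|$. With $B$ the number of
distinct template pairs ($i \ne j$, both indices in $1..N-m$) matching at
length $m$ and $A$ the number still matching at length $m+1$,

$$\mathrm{SampEn}(m,r,N) = -\log(A/B),$$

the negative log conditional probability that an $m$-match extends. Both
counts run over template indices $1..N-m$, so every counted $m$-template
has an $(m+1)$-extension and $A/B$ is a valid conditional probability; the
per-template normalisation constants cancel in the ratio and are never
materialised. Self-matches are excluded. Defaults follow field convention:
$m = 2$, $r \in \{0.10, 0.15, 0.20, 0.25\}$ times the sample SD of the
analysed segment (labelled `SampEn01` … `SampEn025`), and a warning below
100 points, the commonly quoted applicability floor.

**Match criterion.** Textbook prose sometimes writes $d < r$, but the
reference toolkits (Richman–Moorman convention) use $d \le r$. Since
published values in this literature come from such toolkits, `<=` is the
default and `strict_lt = TRUE` is exposed as a switch. On integer-valued
series the two can differ dramatically (the test suite carries a 12-point
fixture where `<=` gives $-\log(7/14)$ and `<` leaves no extended match at
all); on continuous data the difference is negligible.

**Degenerate inputs.** A constant series makes $r = c\cdot\mathrm{SD}$
collapse to zero and is an error instructing the caller to pass an
absolute tolerance; $A = 0$ is *not* an error but an "undefined" result
carried as `NA` with a `defined` flag, so downstream summaries can drop
such subjects explicitly rather than capping the value arbitrarily.

The $O(N^2)$ pair enumeration is implemented in C++ (series run to 4710
points; an exhaustive double loop in R would dominate the test budget).
Its contract is enforced by an independent brute-force R oracle — an
explicit loop over all template pairs — with exact equality on `a_count`,
`b_count` and the value, plus reversal-symmetry and affine-equivariance
property tests.

## Oximetry summaries and desaturation burden

The baseline is the mean of the final 2-minute (exactly 60-sample)
pre-induction window; partial windows are errors, not silently shortened
averages. Desaturation burden below a threshold $\theta = f \cdot
\mathrm{baseline}$ ($f \in \{1.0, 0.9, 0.8\}$) is accumulated by
rectangular integration: each 2-second sample strictly below $\theta$
contributes its full dwell to the duration (min) and $(\theta - x_t)$
times the dwell to the area (min·%). "Strictly below" mirrors the
`<baseline` notation of the clinical literature; samples exactly at
threshold accrue nothing. No interpolation of threshold crossings is
attempted — a deliberate simplicity given 2-second sampling.

**Dropouts.** Acquisition gaps are not discussed in the clinical sources;
our rule is conservative: gaps of at most 10 s are filled by
previous-value carry-forward with a warning, longer gaps invalidate the
series.

## Surrogate-data nonlinearity screen

The per-subject screen asks whether a series is consistent with a
*linear* Gaussian stochastic process observed through a static monotone
function. The null is represented by amplitude-adjusted Fourier-transform
(AAFT) surrogates: gaussianise by rank, randomise Fourier phases
(amplitudes preserved exactly, conjugate symmetry kept), rank-remap back
to the original values. The discriminating statistic is the third-order
time-reversal asymmetry at lag 1,
$\langle (x_{t+1}-x_t)^3 \rangle / \langle (x_{t+1}-x_t)^2 \rangle^{3/2}$,
zero in expectation for any time-reversible (hence any Gaussian linear)
process. With $K$ surrogates the attained two-sided rank p-value is
$2\min(\mathrm{rank}, K+2-\mathrm{rank})/(K+1)$ using the midrank of the
observed statistic; $K = 99$ at $\alpha = 0.05$ rejects exactly when the
observed statistic is more extreme than every surrogate. A $K$ too small
to attain $\alpha$ is a configuration error. The series is linearly
detrended first (surrogate methods assume stationarity); this is
toggleable. The clinical source names only a screening function, not its
settings; these defaults are mainstream surrogate-testing practice and
give an exact-level test, verified by a 200-replicate AR(1) type-I
calibration and a logistic-map power check.

## Cohort statistics layer

* **2×2 tables.** The pivotal undocumented choice in small-cohort
  reporting is *which* categorical test was used per row. The policy here
  — Fisher's exact (two-sided probability-mass rule) when the minimum
  expected count is below 1, Yates-corrected χ² in $[1, 5)$, Pearson χ²
  otherwise — was reverse-engineered to reproduce *all sixteen* printed
  categorical statistics of the reference cohort from their counts to
  ±0.001, and is frozen by an acceptance test.
* **Continuous comparisons.** Pooled-variance Student's t is the default
  ("unpaired t-test" in the sources), Welch is exposed; the Mann–Whitney
  U uses midranks with tie-corrected normal approximation and no
  continuity correction, and requires raw data. Printed t statistics from
  rounded summary tables are only reproducible to ~±0.05, which is the
  tolerance the tests use.
* **Logistic regression.** `glm(binomial)` supplies the MLE (with a
  tightened convergence epsilon so binary-predictor fits agree with the
  closed-form cross-product odds ratio and Wald interval to 1e-6);
  backward likelihood-ratio selection starts from all candidates with
  univariate $p <$ 0.1 and removes the largest-LR-p term until all
  survive at $p \le 0.10$ (the SPSS backward-LR default), recording the
  removal trace. Complete separation is flagged, never silently reported.
* **ROC.** AUC by midrank pair counting (ties count ½), identical by
  construction to $U/(n_+ n_-)$; intervals by DeLong placement values
  (default) or Hanley–McNeil (exposed because legacy SPSS output differs).
  Combined-model discrimination is the ROC of in-sample fitted
  probabilities of a logistic model.
* **AUC power.** Two-sided z-test power with the Hanley–McNeil variance
  ($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$) under null and alternative. For
  the reference design (33 vs 24, 0.5 vs 0.715, α = 0.05) this gives
  0.82, within the 2-point tolerance of the reported 83% — the exact
  variance formula behind that figure is unstated, hence the band.

## The synthetic cohort: what it emulates, what it does not

`generate_series()` composes, on a 2-second grid with a 60-sample
baseline window: a slow sinusoidal drift sitting ~3% below baseline, an
asymmetric slow oscillation (fast desaturation limb, slow recovery —
vasomotion-like), and an AR(1) stochastic component with **negatively
skewed** centred-exponential innovations, mixed by a single irregularity
weight $w \in [0,1]$.

Two deliberate departures from the most obvious model:

* **Skewed innovations / asymmetric waveform.** A Gaussian linear mixture
  would be time-reversible, so the surrogate screen would (correctly)
  retain the null on essentially every generated trace — contradicting
  the predominantly nonlinear dynamics real rSO₂ series exhibit. The
  skewed AR(1) and sawtooth make the process time-irreversible, so the
  generated world sits in the same regime as the data it emulates; the
  test suite requires ≥85% rejection in the POCI group.
* **AR coefficient 0.98.** With a faster-mixing noise term the
  $w \mapsto$ SampEn response is so steep near the clinical targets
  (0.262/0.372 at $r = 0.1$ SD) that per-subject heterogeneity would
  dwarf the group contrast. φ = 0.98 (correlation time ≈ 100 s, a
  plausible slow hemodynamic scale) flattens the response so the
  calibrated weights land at $w \approx 0.11$ and $0.17$ with realistic
  between-subject spread.

Group-level calibration is monotone bisection of $w$ against the mean
SampEn01 of 60 synthetic subjects drawn exactly as the cohort generator
draws them (including the ±0.1 per-subject weight jitter and random
61–157 min durations), under common random numbers; tolerance 0.01. The
residual error is the Monte-Carlo error of 60 subjects, well inside the
0.04 acceptance band at n = 200/group.

MoCA deltas are drawn from small integer supports (3..6 for POCI, −2..2
otherwise, with the preoperative score truncated to [5, 26] so the
education adjustment and the 30-point ceiling can never flip a label);
consequently `classify_poci()` recovers the generated labels exactly, and
the outcome stage is deterministic given the manifest. Covariates are
independent Bernoulli draws at the group prevalences — no attempt is made
to model covariate–covariate correlation.

The generator also has a **feature mode** that draws SampEn01 directly
from the group normal distributions truncated at 0, bypassing signal
synthesis. The large-sample statistical recovery properties (binormal AUC
closed form, per-SD logistic effect coverage) are stated for normal
features and are tested in that mode; the series mode feeds everything
that actually touches signals. Truncation at 0 removes ~2% of the mass of
either group normal, a bias well inside the stated ±0.02 AUC band.

What a green suite does **not** establish: physiological realism of
cerebral autoregulation, clamp/shunt epochs, device artefacts, covariate
correlation structure, or that real rSO₂ entropy differences of the
stated size exist — only that the pipeline measures what it claims on a
world with the stated structure.

## Numerical choices and edge cases

* Windows are half-open `[start, end)` in seconds, 0-based, on a strict
  2-second grid; off-grid timestamps are format errors.
* Series round-trip bit-exactly (`%.17g` formatting).
* `sample(x, 1)` pitfalls in integer supports are avoided with explicit
  index sampling, so a collapsed delta support (pre-MoCA 26) still draws 3.
* All randomness flows from one root seed through
  `substream_seed(root, index)` (a fixed affine fold mod 2³¹−1), so any
  subject or replicate is regenerable in isolation and results are
  byte-identical across reruns of the same seed.
* Bisection endpoints are accepted within the calibration tolerance, so a
  target of 0 in a fully smooth model clamps to $w = 0$ instead of
  erroring on Monte-Carlo noise.

## Known limitations

* The irregularity knob calibrates group *means* of SampEn01; the
  between-subject SD is emergent (jitter, durations, phases) and lands
  near, but is not constrained to, the clinical dispersion.
* In-sample combined-model AUC is reported (as in the source literature);
  no cross-validation or optimism correction is attempted.
* The Mann–Whitney z sign convention follows "group A minus expectation",
  which can differ in sign from other software's group ordering.
* Fisher's method reports no χ² statistic, mirroring the em-dash in
  published tables.
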