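---
title: "Detecting and correcting under-represented cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting under-represented cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Primary-care datasets under-represent some patient groups — through
cultural barriers to contact, differential recording, or collection
procedures. Models trained on such data inherit the gap, and so do
synthetic datasets generated from it. This package implements a
two-stage procedure for tabular health data with one binary disease
target and one discrete protected attribute (ethnicity, region, gender,
age band):

1. **Detection.** A probabilistic classifier is trained on the data
   suspected of bias and applied to a validation set extracted by
   stratified sampling on the protected attribute. Rows whose predicted
   positive-class probability falls in a closed uncertainty band
   \[p1, p2\] form the *uncertain set*. A group whose share among the
   uncertain cases exceeds its share in the suspect data is flagged as
   under-represented: the classifier is disproportionately unsure about
   it.
2. **Correction.** A discrete Bayesian network is learned from the
   suspect data. For every uncertain row, `m` synthetic rows are sampled
   from the network conditioned on evidence taken from that row — its
   protected-attribute value plus its values on the top-k attributes of
   the divergence ordering `O` (non-target variables ranked by the
   distributional distance between the suspect data and the uncertain
   set). The synthetic rows are merged with the suspect data; totals of
   50%, 100% and 200% of the suspect data's size give the three boosted
   datasets.

A companion simulator manufactures datasets with a *known* injected
under-representation, so both stages can be validated by parameter
recovery; SMOTE, AdaSyn and a simplified privileged/unprivileged
Fair-SMOTE serve as comparison resamplers, and an evaluation harness
scores every candidate training set on one fixed held-out test set with
t-based 95% confidence intervals over repeated runs.

## Uncertainty thresholds

The defaults are p1 = 0.4 and p2 = 0.7, interpreted as bounds on the
probability of the **positive** class, with the band closed at both
ends. Optional recalibration repeats a stratified split / train /
predict cycle (10 times by default) and sets p1 to the mean predicted
probability over validation cases in the half-open interval (0.25, 0.5]
and p2 to the mean over (0.5, 0.75], averaged across repeats; an
interval that is empty in every repeat falls back to its default with a
warning, as does a calibrated pair violating p1 < p2. The bundled
classifier is a mixed-data Naive Bayes (Laplace-smoothed categorical
tables with alpha = 1, per-class Gaussians with variances floored at
1e-9); any model exposing train/predict-probability could be
substituted.

## The network engine

All network operations are fully discrete. Numeric variables are
discretized into five empirical-quantile bins (the binning map is kept
for inversion; inverted cells are drawn uniformly within their bin's
interval). How the original study's software handled mixed variables is
not documented; full discretization was chosen here because it makes
every operation exact, enumerable, and testable against brute-force
oracles.

Structure learning is greedy hill climbing over add/remove/reverse
moves scoring BIC, with an in-degree cap of 3, no restarts, and
deterministic first-move-wins tie-breaking. Parameters are maximum
likelihood with Laplace alpha = 1, which keeps every row strictly
positive so likelihood weighting cannot collapse. Forward ("logic")
sampling proceeds in topological order; evidence-conditioned sampling
uses likelihood weighting with `max(1000, 4n)` weighted draws followed
by weighted resampling with replacement (rejection sampling would stall
under many-variable evidence), warning when the effective sample size
falls below n/10. Exact conditional marginals by joint enumeration
(capped at 1e6 states) serve as the test oracle throughout.

**Exogenous protected attribute.** When a generative network is learned
for bias injection or boosting, the protected attribute is constrained
to be a root (no incoming edges). BIC orientation otherwise always
points disease-protected edges *into* a high-cardinality protected node
— the penalty for adding a binary parent to a 10-level node is an order
of magnitude smaller than the reverse — and rewriting the conditional
table of a node with parents severs exactly the dependence the method
needs to preserve. Treating demographics as exogenous causes is
standard practice in epidemiological network modelling and makes the
marginal override well defined: forcing a root's distribution changes
group sizes while leaving every group-conditional distribution intact.

## Bias injection

Given a target marginal over the protected levels, the simulator
learns a network from the source data, overrides the protected node's
distribution, samples an intermediate dataset, then learns a *second*
network from that sample and draws the final biased dataset from it, so
no original row survives into the output. The realized protected
marginal is checked against the target within 3 binomial standard
errors (a warning, not an abort, since with 10 levels a 3-SE band is
occasionally exceeded by chance). An evidence-based mechanism
(per-level quotas via likelihood weighting) is available as an
alternative; the override is the default. The intermediate sample size
defaults to the output size.

## Boosting details

- Totals are `round(fraction * n)` with round-half-up; the per-row
  counts `m_i` differ by at most one, with the remainder assigned to the
  lowest-index uncertain rows.
- Evidence depth k defaults to 3: the protected value plus the top-3
  variables of `O` (numeric evidence values are mapped to their bins,
  clamped to the end bins outside the observed range). The source text
  does not say which variables the evidence uses; clamping the
  highest-divergence attributes targets exactly the distributions the
  uncertain set says are missing, and k is tunable from 0 to all.
- The target is never used as evidence, so boosted data cannot leak
  validation labels; synthetic rows receive sampled labels.
- Identical evidence configurations are pooled into one sampling call.
  Contradictory evidence falls back to the protected attribute alone,
  then to skipping the row with its count redistributed (both logged).
- Uncertain rows themselves are not copied into the output: the boosted
  dataset is the suspect data (provenance `original`) plus the
  synthetic rows (provenance `synthetic`).

## The fixture generators

`make_cvd_like()` draws from a pinned, hand-authored network
(committed as YAML under `inst/extdata/`) over gender, a 10-level
ethnicity, a 10-level region, banded age/BMI/systolic blood pressure
(inverted to numerics uniformly within bands), smoking, and three
binary diseases whose conditional probabilities follow logistic forms
in age, smoking, BMI and ethnicity. The ethnicity baseline is heavily
skewed (0.78 for the reference level, one 0.12 minority level, the
rest spread over eight small groups; the tenth level, "Mixed", is a
naming guess documented here rather than asserted as any registry's
category). Disease prevalences sit in the 5-20% band with positives the
minority class. `make_covid_like()` generates gender, region, age with
derived age bands, and a diagnosis target. Everything downstream is
testable by parameter recovery because the generating distribution is
known exactly and enumerable (384,000 joint states).

Two emulation choices deserve emphasis. First, the ethnicity-disease
log-odds effects (≈1.5 for the South Asian analog levels) are at the
high end of what primary-care studies report. They are set so that the
dependence survives BIC structure learning at the fixture's scale
(n ≈ 20,000): the BIC penalty for an ethnicity-disease edge is fixed at
roughly `0.5 log(n)` per parameter while the evidence grows linearly in
n, so at registry scale (hundreds of thousands of rows) weaker
real-world effects clear the same bar. Second, the fixture's ground
truth is itself a network sample, which means regeneration through a
learned network is nearly lossless — see limitations.

What passing tests show, therefore, is that the machinery detects and
corrects a known injected under-representation on data whose dependence
structure a discrete network can represent. They do not show how the
procedure behaves under real-data features the fixtures lack:
continuous within-band risk gradients, missingness, label noise,
longitudinal structure, or dependencies a sparse discrete network
cannot carry.

## Evaluation design

Candidates are compared by training the same Naive Bayes classifier on
each and scoring one fixed, held-out 30% test partition (split
stratified on the target). "Ten runs" re-randomizes candidate
generation and any resampling ties while the test set stays fixed;
confidence intervals are `mean ± t(0.975, n-1) · sd/√n`. Thresholded
metrics use 0.5. ROC-AUC is the rank statistic (equivalent to the
trapezoid rule with midrank ties); PR-AUC uses step interpolation over
distinct thresholds. Group-fairness diagnostics report the
demographic-parity gap (max-min per-group positive-prediction rate) and
the equalized-odds gap (the worse of the TPR and FPR ranges).
`fairness_uncertain_set()` implements the experimental alternative of
selecting "uncertain" cases from the most disadvantaged group under one
of those gaps, capped at the size the probability-band filter would
have chosen; it is a labelled reconstruction, kept out of the default
pipeline.

## Known limitations

- **The unbiased-vs-biased accuracy ordering does not reproduce on
  network-generated fixtures.** On real-scale data, regenerating a
  dataset through a learned generator loses real structure, and a
  classifier trained on the regenerated data performs measurably worse.
  The fixture's ground truth is itself a network sample, so the
  two-network injection loses essentially nothing; the acceptance suite
  documents this by computing the comparison and letting it fail. In
  fact a Naive Bayes model trained on a resample here scores slightly
  *higher* on held-out data than one trained on the source draw,
  because resampling smooths the numerics and flattens redundant
  correlated-evidence likelihood ratios that Naive Bayes double-counts.
  The boosted-vs-biased and boosted-vs-resampler orderings are
  unaffected and are asserted.
- One discrete protected attribute at a time; binary targets only.
- The divergence-ordering evidence rule (protected + top-k of `O`) is a
  reconstruction: the source text defines `O` but not how it is
  consumed.
- Problem sizes used by the test suite (fixtures of 1,500-20,000 rows,
  ten-seed recovery loops, 50,000-draw sampler checks) were chosen so
  the whole suite runs in a few minutes on one CPU while keeping every
  stochastic tolerance at 3 standard errors.
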