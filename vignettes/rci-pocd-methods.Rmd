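---
title: "Methods: control-referenced reliable change and perioperative cognitive outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: control-referenced reliable change and perioperative cognitive outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periCog)
```

## The problem

Postoperative cognitive dysfunction (POCD) — a measurable decline in
cognitive performance a few months after surgery — and preoperative
cognitive impairment (preCI) are dichotomous outcomes built from a
multi-test neuropsychological battery. Deciding that a patient *declined*
is not trivial: healthy people improve on retest (practice effects) and
test scores fluctuate. The reliable change index (RCI) approach handles
both by referencing every patient's change score to the retest behaviour
of a non-surgical control group.

periCog implements that pipeline end to end: battery orientation and
transforms, the control-referenced Z-scores and the composite, the
dichotomization rule, the covariate-adjusted association models (odds
ratio of impairment per cm³ of thalamus volume, with ROC/AUC and VIF
diagnostics), the cohort flow accounting, and a synthetic cohort
generator with known ground truth, so every stage is testable without
restricted patient data.

## The battery and its orientation

Seven parameters: paired-associates memory score (PAL), verbal free
recall and delayed recognition (VRM, word counts), spatial span (SSP),
grooved pegboard time (GPT, s), simple reaction time of correct trials
(SRT, ms) and trail-making part B time (TMT-B, s). The three timed
measures are log-transformed (natural log — the base cancels in any
Z-score, so only the convention matters) and reversed by negation, so on
the oriented scale **higher is always better** and a decline is always
negative:

$$\tilde{x} = \begin{cases} x & \text{untimed} \\ -\ln x & \text{timed.} \end{cases}$$

TMT-B administrations lasting 300 s (180 s for part A) were terminated,
so such values carry no usable time and become *excluded-missing* before
orientation (`apply_timeout_rule()`; the boundary itself is excluded,
since termination happens at the limit). SRT is scored as the mean
latency of correct trials in ms: the battery description mentions trial
counts, but the analysis list and the reported magnitudes (~309) are
latencies, and the latency reading is the one implemented.

## The reliable change model

Let $\Delta\tilde{x}_{ip}$ be patient $i$'s oriented follow-up minus
baseline value on parameter $p$, and let $\bar{c}_p, s_p$ be the mean and
sample SD (denominator $n-1$) of the same quantity over controls. Then

$$Z_{ip} = \frac{\bar{c}_p - \Delta\tilde{x}_{ip}}{s_p},$$

so deterioration *beyond the control practice effect* is positive. The
composite ("total") Z is the sum of the available per-parameter Z's,
rescaled by the control-group SD of that same sum,

$$Z_i^{tot} = \frac{\sum_{p \in A_i} Z_{ip}}{\mathrm{SD}_{ctrl}\!\left(\sum_{p \in A_i} Z_p\right)},$$

which keeps its null SD at 1 whatever the inter-test correlation.
preCI uses the identical construction on baseline *levels*, referenced to
the control baseline session (not pooled sessions — a package choice; the
source method leaves it open).

A subject is **impaired** when $Z^{tot} > 1.96$ and/or $Z_{ip} > 1.96$ on
$\ge 2$ individual parameters; the inequality is strict, and the
`criterion` field records which clause fired. Subjects with fewer than 5
of 7 available parameters are explicitly *unclassifiable* — never
silently "not impaired". For subjects missing items, the composite
denominator is recomputed over controls complete on the same subset
(cached per subset), the choice that keeps the subset composite's null SD
at 1; whether the original analysis did this is unknown, so it is a
documented package decision.

No multiplicity correction is applied across the 7 parameters: the rule
*is* the decision procedure, and its family-wise behaviour is surfaced
instead by `null_false_positive_rate()` — under the independent-normal
null the $\ge$2-of-7 clause alone fires with probability
$1 - 0.975^7 - 7(0.025)(0.975^6) \approx 0.0121$, and the full two-clause
rule lands between 0.02 and 0.05.

## Association models

Logistic regressions (maximum likelihood via IRLS) of preCI and POCD on
thalamus volume, unadjusted and adjusted for age, sex and intracranial
volume; OR per cm³ = $e^\beta$ with Wald 95% CI $e^{\beta \pm 1.96\,SE}$
(Wald intervals match the symmetric-on-log-scale intervals the emulated
analysis reports). Complete-case (listwise) deletion per model, matching
the varying per-model n of the original. Model accuracy is the ROC AUC of
the fitted probabilities, computed as the Mann–Whitney concordance with
ties counted half; its p-value uses the normal approximation to the U
test with tie correction (the original's AUC test is unnamed — a package
decision). Multicollinearity is screened with $VIF_j = 1/(1 - R^2_j)$,
flagged above 2.5. Perfect separation is reported as non-convergence,
never silently. Sex is coded 0/1 with female = 1; surgery severity and
type enter the sensitivity model as indicator contrasts.

The continuous sensitivity analyses standardize each parameter against a
reference surgical population's mean/SD and *average* the available z's
(this composite deliberately differs from the RCI sum-composite), then
fit OLS of baseline, follow-up and change composites on thalamus volume
with the same covariates. The original reference population (928 surgical
patients) is restricted data; by default the analysed cohort itself is
the stand-in reference, and `composite_reference=` accepts a larger one.

## The synthetic cohort: a stated world

The generator exists so that ground truth is known. Its defaults are the
emulated study's published descriptives, fixed once:

* cohort sizes 301 surgical / 114 control, follow-up rate 0.704;
* age 72.4 (SD 4.9) years, 43.5% female, thalamus 12.9 (SD 1.6) cm³,
  intracranial volume 1339.0 (SD 212.4) cm³, thalamus–ICV correlation 0.5
  (unstated in the source; volumes scale with head size);
* battery levels/spreads from the unimpaired patient stratum (e.g. PAL
  14.0 ± 4.2, GPT 93.1 ± 24.7 s, SRT 309.0 ± 89.6 ms, TMT-B
  112.3 ± 39.1 s), with timed parameters generated log-normal (delta
  method for the log-scale SD);
* learning effects from the unimpaired baseline-to-follow-up shifts
  (e.g. PAL +1.5 points, GPT $\ln(93.1/88.0) \approx 0.056$ log-units);
* retest noise $\sqrt{0.5}$ × the cross-sectional oriented SD, i.e.
  test–retest reliability ≈ 0.75, a typical value for these instruments;
* inter-test equicorrelation 0.3 (one positive-definite knob; the source
  reports no covariance structure), item missingness 5%;
* prevalences 11.3% (preCI) / 11.8% (POCD), injected as an additive shift
  of 3 control-SDs on 3 randomly chosen parameters per impaired subject
  (baseline SDs for preCI, change SDs for POCD) — the simplest mechanism
  with controllable detectability; the source only classifies, it never
  specifies a decline process;
* thalamus volume enters the impairment probability through a log-odds
  slope per cm³, default 0 (the null result as a property); the POCD
  truth follows an exact logistic law so coefficient recovery is testable;
* loss to follow-up completely at random by default — matching the
  analysis's own missing-at-random assumption — with an optional
  age-weighted dropout (`dropout_age_weight`) off by default, since the
  original cohort's dropout was plausibly informative.

What a green test establishes: the pipeline's internal consistency
(controls score 0 ± 1 against themselves), calibration of the rule's null
behaviour, recovery of injected effects, and correctness of the closed
forms. What it does not: anything about real patients — the generator has
Gaussian margins, a single equicorrelation, no comorbidities, no
informative dropout by default, continuous rather than integer scores,
and disjoint preCI/POCD truth (the real cohort had one overlap).

## Numerical and reporting choices

* **Rounding**: percentages are rounded half-up to one decimal in one
  single code path (`percentage()`); this reproduces every published
  count/percentage pair except one — 89/301 is printed as 29.5% although
  the arithmetic gives 29.568 → 29.6; the package reports 29.6.
* **Quartiles**: the $(n{+}1)p$ linear-interpolation convention
  (`quantile type 6`), under which $\{1,2,3,4,100\}$ has IQR 1.5–52;
  configurable only by editing `iqr_vars`/the convention, documented here.
* **Flow percentages**: the source text mixes denominators for the loss
  subcategories, so the ledger stores raw counts and
  `flow_percentages()` always names its denominator.
* **Strict threshold**: Z exactly 1.96 is *not* impaired.
* **Orientation**: negation after log; any order-reversing convention
  yields identical |Z|.

## Known limitations

* Sensitivity of the POCD label at a 3-SD decline on 3 parameters is
  ≈ 0.94 when parameters are independent but ≈ 0.89 at the default
  equicorrelation 0.3 — correlated Z's make misses co-occur. The
  detection benchmark in the acceptance suite therefore runs under the
  independence condition its closed-form derivation assumes.
* At 2 affected parameters the ≥2-of-$k$ clause alone detects a 3-SD
  decline with probability ≈ 0.72; high sensitivity requires ≥ 3 affected
  parameters or the composite clause.
* The classifier's false-positive rate under the generator's *default*
  (correlated) null exceeds the independent-null rate; both are
  measurable with `null_false_positive_rate()` and a zero-injection run.
* MRI segmentation, delirium adjudication and any alternative POCD
  definitions (1-SD rules, regression-based RCI) are out of scope; the
  threshold is configurable but 1.96 everywhere by default.
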