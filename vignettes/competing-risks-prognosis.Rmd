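---
title: "Absolute risk of metastatic death from choroidal melanoma: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute risk of metastatic death from choroidal melanoma: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crprog)
```

## The clinical problem

Roughly half of all patients with choroidal melanoma eventually die of
metastatic disease, and the risk varies enormously between patients: from
about 1% to about 80% at ten years. The two single most informative
predictors are the largest basal tumor diameter (LBTD) and the tumor's
chromosome 3 status (C3S): loss of one copy of chromosome 3 (monosomy 3, M3)
multiplies the metastatic hazard roughly tenfold relative to disomy 3 (D3).
Many patients, however, never have their tumor genetically typed —
particularly those with small tumors — so a usable prognostic system must
work both with and without C3S, and must not overstate metastatic risk in
elderly patients who are likely to die of something else first.

crprog estimates the *absolute risk* (cumulative incidence) of metastatic
death in the presence of the competing risk of other-cause death, for groups
defined by a six-level LBTD factor, optionally crossed with C3S, and
presents the results as paper-form prognostic tables at 2, 5 and 10 years.

## The estimator

Patients are grouped by LBTD bin (edges at 10, 12, 14, 16, 18 mm; intervals
left-open/right-closed so a 12.0 mm tumor falls in "10.1–12.0") and, when
C3S enters the model, by LBTD × C3S (12 groups). Within group $k$ the
absolute risk of metastatic death is the Aalen–Johansen estimator

$$\hat F_k(t) = \sum_{u \le t} \hat S_k(u^-)\, \frac{\Delta N_k(u)}{Y_k(u)},$$

where $\Delta N_k(u)$ counts metastatic deaths at $u$, $Y_k(u)$ is the
number still at risk just before $u$, and $\hat S_k(u^-)$ is the left limit
of the group's own all-cause Kaplan–Meier survival. No independence
assumption is made about the competing risk. Deaths of both causes at the
same time share one at-risk set; censorings at a death time are processed
after the deaths. The identity $\hat F_{\text{met}} + \hat F_{\text{oth}} +
\hat S_{\text{KM}} = 1$ holds algebraically at every event time and is
asserted in the test suite to $10^{-12}$.

Cause of death is coded by a conservative registry rule: only "definite" or
"probable" metastatic uveal melanoma counts as metastatic death; "possible"
metastasis, other malignancies, non-cancerous causes and unknown causes are
other-cause deaths, and patients alive at last follow-up are censored.
Coding the *unknown* category as other-cause death (rather than excluding
it) follows from the rule that melanoma death requires positive evidence;
the alternative — dropping those deaths — would bias both cumulative
incidences downward.

### Age adjustment of the competing hazard

Other-cause mortality rises sharply after 80 years of age, which *lowers*
the absolute metastatic risk of older patients with identical tumors. The
other-cause hazard is modelled semiparametrically: a Cox partial-likelihood
fit on the binary age factor (≤80 vs >80 at treatment, labelled "<81 yr" /
">80 yr"; exactly 80 is "≤80") with a Breslow baseline. Age-specific
absolute risks are then obtained by the product-integral composition

$$\hat S(u) = \prod_{v \le u}\bigl(1 - \Delta\hat\Lambda_{\text{met},k}(v) -
e^{\beta z}\,\Delta\hat\Lambda_{\text{oth},0}(v)\bigr), \qquad
\hat F_{k,z}(t) = \sum_{u \le t} \hat S(u^-)\,
\Delta\hat\Lambda_{\text{met},k}(u),$$

with $z$ the age indicator. Sharing one cohort-wide other-cause hazard
across groups (scaled by the age hazard ratio) rather than splitting each
group by age keeps the small cells estimable; when the age coefficient is
zero and the baseline hazard is taken from the group's own data, the
composition reduces exactly to the group's Aalen–Johansen estimate, which
the tests verify. Survival factors are clipped into $[0,1]$, which matters
only for pathologically sparse inputs. This composition is deliberately
isolated in a single function (`combine_cif_with_cox()`) so an alternative
age treatment can be swapped in without touching anything else.

## Missing chromosome 3 status

In referral cohorts like the one this package is designed around, roughly
three quarters of patients have unknown C3S, and the missingness is
*informative about size*: small tumors are less often typed, and small
tumors are more often D3. Dropping untyped patients would therefore bias
the analysis. Missing C3S is handled by approximate Bayesian multiple
imputation:

1. a logistic model for $P(\text{M3})$ given LBTD bin, event-type
   indicators and log follow-up time is fitted on the typed patients
   (outcome terms are included so the imputation is compatible with the
   survival analyses downstream);
2. for each of $M$ datasets, coefficients are drawn from the normal
   approximation to their posterior (mean = estimate, covariance =
   estimated covariance) and each missing C3S is drawn Bernoulli — this
   fresh coefficient draw per dataset is what makes the imputation
   "proper";
3. point estimates average the per-dataset estimates:
   $\bar F_k(t) = M^{-1}\sum_i \hat F_k^{(i)}(t)$.

Observed C3S values are never altered, which the suite asserts dataset by
dataset. Under separation (e.g. a bin whose typed patients are all M3) the
fit falls back to a lightly ridge-penalised logistic regression with a
warning.

Confidence intervals use the pooled-sample MI bootstrap: within each
completed dataset, subjects are resampled with replacement $B$ times and
the estimator re-evaluated; all $M \times B$ values per cell form one
empirical distribution whose 2.5 and 97.5 percentiles are the limits. All
bootstrap draws are pooled rather than combined by Rubin's rules because
the interval is a percentile interval, not a variance-based one. The
analysis-scale profile is $M = 101$, $B = 2000$; development and testing
use $M \in [5, 11]$, $B \in [20, 200]$, which leaves the point estimates
essentially unchanged and widens Monte-Carlo noise on the interval
endpoints only slightly.

## Factor ranking

Candidate risk factors are ranked by *rescaled AIC*: the likelihood-ratio
chi-square for deleting the factor from a cause-specific Cox model, minus
twice the degrees of freedom it costs. Positive values mean the factor
carries more information than its complexity; under the null the expected
value is $-\mathrm{df}$, so negative values signal overfitting risk (the
suite checks the $-1$ null mean for a 1-df noise factor by simulation).
Backward selection repeatedly deletes the factor with the most negative
value until all remaining values are positive. Because the published
convention does not pin down whether rankings come from the sequential
deletion path or from single deletions from the full model, both are
implemented (`method = "sequential"` default, `"single"` alternative);
they agree on well-separated data. With missing C3S, selection runs within
each imputed dataset and the values are averaged.

## The synthetic cohort generator

No individual-level cohort is distributed with the package, so all
statistical validation runs against `simulate_cohort()`, whose defaults
were fixed from the published cohort description before any testing and
are not tuning knobs:

* LBTD lognormal, median 12 mm, IQR ≈ 9.6–14.8 mm, truncated to
  2.4–28 mm; age truncated-normal (mean 63, sd 14 years, about 11% over
  80);
* monosomy-3 prevalence rising with LBTD bin (0.22, 0.29, 0.45, 0.57,
  0.64, 0.79), taken from the typed strata of the published crude table;
* probability that C3S is untyped falling with LBTD bin (0.85 … 0.64,
  about three quarters missing overall) — missing-at-random given the
  observed LBTD, matching the reported mechanism; an optional
  outcome-dependent shift exists solely for sensitivity experiments;
* constant (exponential) cause-specific hazards per LBTD × C3S cell for
  metastatic death (0.002–0.022/yr under D3, 0.033–0.23/yr under M3) and
  per age bin for other-cause death (0.02 vs 0.09/yr), chosen so 10-year
  risks span the published range (≈1% to ≈80%);
* independent exponential censoring (0.08/yr) plus a 25-year
  administrative horizon.

Constant hazards were chosen deliberately: the true cumulative incidence
then has the closed form $F_{\text{met}}(t) = \frac{\lambda_m}{\lambda_m +
\lambda_o}\bigl(1 - e^{-(\lambda_m+\lambda_o)t}\bigr)$ (`true_cif()`),
giving exact oracles for consistency, imputation-recovery and
bootstrap-coverage tests. The generator also emits realistic correlated
covariates (thickness, chromosome 8q, histology) that never enter the
hazards, so they serve as noise factors in selection experiments.

What the generator does *not* emulate: non-constant (e.g. accelerating)
metastatic hazards, calendar-time referral drift, dependence between
censoring and covariates, and misclassified causes of death. Passing tests
therefore demonstrate that the estimation machinery recovers a known truth
under the model's assumptions — not that those assumptions hold in any
particular clinic's data.

## Numerical and design notes

* **Problem sizes.** The validation suite uses n = 5000 for consistency
  and selection recovery (50 replicates), n = 4000 for MI recovery at 40%
  missingness (M = 11), and 200 replicates at n = 400 (M = 5, B = 100) for
  bootstrap coverage of one mid-size cell, chosen as comfortable desk-scale
  settings with Monte-Carlo error well below the assertion margins.
* **Ties and zero cells.** Tied death times of different causes share one
  at-risk set; a bootstrap resample that empties a group contributes a
  zero curve (nothing observable) and is counted, not dropped. A resample
  with no comparable pairs for the C-index is skipped and counted.
* **Degenerate inputs.** A cohort with no other-cause deaths cannot
  identify the age model and errors; no events of one age stratum gives a
  monotone likelihood, flagged with the coefficient capped. Empty table
  cells are reported as unavailable ("—"), never fabricated.
* **Concordance definition.** The fixed-horizon competing-risks C-index
  treats a patient with a competing event as known event-free for the
  cause of interest at all horizons; patients censored before the index
  patient's death are non-comparable, and no censoring weighting is
  applied. An exhaustive pair-enumeration oracle in the tests pins this
  definition exactly; ties in the risk score count one half, so an
  all-tied score gives C = 0.5 identically.
* **Display conventions.** Crude percentages round half-up to one decimal
  (26.25 → 26.3); table risks print to one decimal below 10% and two
  significant figures above.
* **Known limitations.** The imputation model's covariate set (LBTD bin,
  event indicators, log time) is a documented choice, swappable but not
  exhaustive; no Fine–Gray regression, hazard smoothing or IPCW-weighted
  concordance is provided; the "unknown C3S" table panel is the marginal
  LBTD-only estimate, not an average of the D3 and M3 panels, because that
  is how the two-model system is meant to be used when genetics are
  unavailable.
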