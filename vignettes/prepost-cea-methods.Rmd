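---
title: "Methods: pre-post cost-effectiveness analysis for severe asthma biologics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-post cost-effectiveness analysis for severe asthma biologics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis design

prepostCE implements a patient-level *pre-post* pharmacoeconomic
evaluation: each patient contributes one baseline year (standard therapy)
and one treatment year (add-on biologic, here benralizumab for refractory
eosinophilic asthma), and the treatment year is compared against the
baseline year of the *same* patients. This is the design used in
real-life biologic evaluations where no concurrent control arm exists.
Its key analytical consequence is that all uncertainty statements must
respect the pairing: bootstrap resampling draws whole patients (both
periods together), and paired effect sizes are available.

Three effectiveness measures are supported, in the units a Spanish payer
evaluates them:

* **severe exacerbations avoided** (count per patient-year; a severe
  exacerbation requires at least 3 days of systemic corticosteroids
  and/or emergency care);
* **ACT points** (Asthma Control Test, 5 = uncontrolled to 25 = complete
  control; 20 is the controlled-asthma threshold and 3 points the minimal
  clinically important difference), also expressed as the
  *effectiveness rate* ACT/25;
* **utility** mapped from asthma control (0.91 controlled / 0.73
  uncontrolled, Spanish EQ-5D weights for severe asthma), accumulated
  into QALYs over the 1-year horizon without discounting.

Decision statistics are the standard set: the incremental
cost-effectiveness ratio ICER = (C_post - C_pre)/(E_post - E_pre), the
cost-effectiveness plane with NE/SE/NW/SW quadrants and dominance labels,
the net monetary benefit NMB = dE x WTP - dC and net health benefit
NHB = dE - dC/WTP (identically NMB/WTP), with the Spanish
willingness-to-pay range of 22,000-24,000 euros per QALY shipped as
presets and 24,000 as the default. A zero effectiveness difference leaves
the ICER undefined; the package returns `NA` with a pointer to the
net-benefit statistics rather than an infinity, and the plane labelling
is made total by assigning axis points to dominant/dominated/equivalent.

## The synthetic cohort generator

No patient-level data accompany the published study, so the package
ships a generator whose default calibration
(`default_cohort_params()`) *is* the study condition: 44 patients with
the published means and SDs for every clinical variable and every annual
cost category in both periods, and the published Pearson correlations
between the baseline severe-exacerbation count and the baseline OCS cost
(0.839) and emergency-care cost (0.849).

The joint distribution is a Gaussian copula over one latent dimension
per variable-period, with marginal families chosen by variable type:

* counts (exacerbations, emergency visits, admissions, hospital days,
  OCS courses): negative binomial parameterised by (mean, SD), because
  exacerbation counts are overdispersed (5.50 with SD 2.63 at baseline);
  the generator falls back to Poisson when SD^2 <= mean, where the
  negative binomial is undefined;
* doses and annual costs: gamma (non-negative, right-skewed, SD of the
  same order as the mean, as in the published cost table). The
  treatment-year maintenance OCS dose is zero-inflated gamma with 70%
  exact zeros — close to the largest zero fraction compatible with the
  published cohort-wide mean and SD, which are preserved exactly —
  because most patients discontinue maintenance corticosteroids on the
  biologic and the response classification hinges on an exact zero;
* FEV1 (mL and % predicted): normal truncated at zero — the truncation
  sits beyond 2.8 SD, so the induced moment bias is below 0.3%;
* ACT: a truncated normal on [5, 25] discretised to integers. Raw
  truncation would bias the treatment-period mean by about 1% (the upper
  bound is only 1.7 SD above the mean), so the latent (mu, sigma) are
  solved numerically so the *discrete* marginal matches the target mean
  and SD exactly.

Three numerical choices deserve explanation.

**Correlation feasibility.** The two published correlation targets share
a variable. With the unspecified third correlation (OCS cost vs
emergency-care cost) set to zero, the 3x3 correlation block is not
positive semi-definite (0.839^2 + 0.849^2 > 1), and a nearest-PSD repair
would drag the published targets away from their values. The preset
therefore closes the triangle with the product 0.839 x 0.849 — i.e.
conditional independence of the two cost categories given the
exacerbation count, a one-factor structure in which exacerbations drive
both acute-care cost categories. This is also the clinically natural
reading. For user-supplied parameter sets, unspecified correlations
default to zero and a nearest-PSD repair is applied, with an error if
repair fails.

**Latent-correlation matching.** Pearson correlations are attenuated by
the marginal quantile transforms, noticeably so for discrete counts
(a latent 0.839 yields roughly 0.82 after the negative-binomial
transform). Requested targets are therefore matched on the *output*
scale: the latent correlation is solved by quadrature of
E[F1^-1(Phi(Z1)) F2^-1(Phi(Z2))] over the bivariate normal. A dense
trapezoidal grid is used rather than Gauss-Hermite nodes because count
quantile functions are step functions, for which Gaussian quadrature is
badly biased.

**Stratified marginals.** Plain i.i.d. sampling leaves relative
standard errors above 1% for small-mean count variables even at
n = 100,000. The generator therefore uses Latin-hypercube stratified
uniforms reordered by the copula ranks (Iman-Conover style), which keeps
the rank dependence while making every marginal's sample moments converge
at rate 1/n. This is standard practice in probabilistic sensitivity
analysis and can be disabled (`stratified = FALSE`).

**Pre-post linkage.** The source study is silent on the within-patient
correlation between years. The preset links the two periods
autoregressively on the latent scale: the treatment-year latent score is
`pre_post_rho` times the baseline score plus independent innovation, so
the same-variable pre-post copula correlation equals `pre_post_rho`
(default 0.5, an explicit parameter, deliberately not tuned) and
cross-variable structure decays with it.

Quantities the study does not print are imputed once and documented: the
treatment-year admission and hospital-day marginals are scaled from the
published admission-cost ratio and the pneumology per-day rate; the
baseline biologic mix (16 omalizumab / 5 mepolizumab / 2 both / 21 none)
labels patients for realism while the baseline biologic *cost* is a
calibrated gamma marginal, because the published mean (7,151.63 euros) is
not recoverable from full-year drug prices (part-year exposure is the
likely cause). Corticosteroid dependence is assigned to the patients with
the highest maintenance dose at the published proportions (18/44 and
8/44), which enforces the dose-flag consistency invariant by
construction.

What the generator deliberately does **not** emulate: within-year timing
of exacerbations (annual aggregates only, matching the 1-year horizon);
zero-inflation of cost categories (a patient with no admission still
draws a small positive admission cost from the gamma marginal); and any
correlation the study does not report (all other pairs are independent
given the copula structure). Passing tests on this cohort therefore
demonstrate correctness of the *pipeline* at the published calibration,
not distributional fidelity to the unpublished patient-level data.

## Costing conventions

All euro arithmetic is carried in integer cents and rounded to the cent
exactly once per category, so the breakdown total equals the category sum
exactly. The 2020 unit-cost schedule is packaged both in code
(`default_unit_costs()`) and as YAML (`inst/extdata/unit_costs_2020.yaml`).

Where the publication is silent, the convention is an explicit schedule
parameter:

* maintenance OCS is priced per mg-day scaled from the 5 mg, 7-day course
  price (11.86/7 euros per 5 mg-day); exacerbation courses are priced
  separately at the 30 mg course price;
* ICS annual cost is daily micrograms x 365 / (200 ug x 200 puffs per
  pack) x 36.96 euros;
* hospital days default to the pneumology per-day rate (386.65 euros),
  with the general rate selectable.

The published analysis uses two cost aggregates that differ (a total of
11,544/14,043 euros and an exacerbation-analysis basis of 10,292/13,204
euros) without identifying the excluded components; the difference is not
exactly recoverable from the published categories. The cost basis is
therefore a named parameter (`cost_basis = "total"` or
`"exacerbation_related"`, the latter defined as total minus scheduled
diagnostics minus ICS), and the published figures can always be supplied
directly as inputs to the deterministic functions.

Dosing arithmetic (`doses_in_first_year()`) counts administrations in
weeks 0-51 with the first dose at week 0; the benralizumab descriptor
(30 mg every 4 weeks for 3 doses, then every 8 weeks) yields 8 first-year
doses, consistent with the published annual cost per dose.

## Response classification

The Spanish severe-asthma consensus defines four response categories
(complete response, controlled asthma, partial response, no response)
by criteria on exacerbations, ACT, FEV1 and systemic corticosteroids,
but does not state a combination rule, and its partial-response row is
ambiguous. The package evaluates categories best-to-worst with
conjunctive criteria; the first full match wins. The partial-response
predicate — exacerbation improvement (>= 50% reduction or fewer than 2
severe exacerbations), plus a symptomatic or functional gain (ACT +3, or
ACT >= 20, or FEV1 gain > 10% and > 100 mL), plus an OCS dose reduction
> 50% or discontinuation — matches the nine partial responders described
in the source study (eight still corticosteroid-dependent with >= 50%
dose reduction, one discontinued). Every threshold lives in
`response_rules()` and can be overridden, and `classify_cohort()` exports
the per-criterion booleans for audit. The rule set is monotone: improving
any single treatment-year outcome never demotes the category
(property-tested).

## Utility mapping

The dichotomous map (0.91 if ACT >= 20 else 0.73) is the published
method and the default. It cannot, however, reproduce the published
cohort-mean utilities (0.729 baseline / 0.867 treatment) from the
published control proportions (2/44 controlled at baseline gives 0.738),
so the true patient-level mapping is unrecoverable. An `act_linear` mode
(linear between ACT 5 at 0.73 and ACT 25 at 0.91) is shipped as a
smooth alternative; the discrepancy is documented, not resolved. For the
deterministic worked examples the published mean utilities are simply
used as inputs.

## Uncertainty quantification

**Bootstrap.** ICER confidence intervals use the percentile bootstrap:
patients are resampled with replacement at the original size, the ICER
is recomputed per replicate, and the 2.5th/97.5th percentiles are
reported (10,000 replicates by default). Replicates with zero mean
incremental effectiveness have no defined ratio; they are dropped and
counted, and a net-monetary-benefit bootstrap (which has no degenerate
replicates) is offered as the alternative. On a 3-patient cohort the
empirical percentiles are verified against exhaustive enumeration of all
27 ordered resamples.

**PSA.** The first-order Monte Carlo simulation draws, for each of
10,000 hypothetical patients (the default, a parameter), independent
annual costs for both regimens and independent effectiveness for both
regimens, from distributions parameterised by the cohort summaries:
gamma for costs, normal truncated to the measure's valid range for
effectiveness. The distribution families are a design choice the source
publication does not state, and both are configurable. Outputs are the
incremental-pair scatter (the cost-effectiveness plane), the probability
of positive NMB at given thresholds, the acceptability curve over a WTP
grid, and the dominant-quadrant fraction. The published PSA
probabilities (99.8% ACT-based, 80.9% utility-based) and dominance
fractions (about 10% and 8.3%) depend on the unpublished patient-level
joint distribution of costs and effects; they are qualitative references
only, and the package makes no attempt to tune toward them.

**Effect sizes.** Paired Cohen's d is computed as
(mean_pre - mean_post)/denominator with three denominator conventions:
SD of the paired differences (default), pooled SD, and baseline SD. No
printed convention reproduces the published d = 2.00 for exacerbations
from the printed SDs (pooled gives about 2.45, baseline-SD about 1.84),
which is why all three are shipped and the convention is always reported
alongside the value. Magnitudes are banded at
0.15/0.40/0.75/1.10/1.45; the published band list leaves d = 1.45
unassigned, and the package closes the gap upward (>= 1.45 is
"enormous"). Bands are applied to |d| so the banding is total on the
real line.

## Numerical and reproducibility choices

* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; the same seed gives bit-identical output, and the
  pipeline's headline JSON is byte-identical across runs.
* Default problem sizes: cohort 44 (the study size), moment-recovery
  checks at n = 100,000, bootstrap 10,000 replicates, PSA 10,000
  simulated patients. The test suite uses smaller sizes where the
  property under test does not require scale.
* Currency arithmetic in integer cents; headline ratios are reported
  unrounded, with rounding applied only at presentation.
* Degenerate inputs are first-class: empty cohorts, zero-variance
  distributions, single-replicate bootstraps and zero effectiveness
  differences all either return well-defined values or raise typed
  validation errors naming the offending input.

## Known limitations

* The generator matches first and second moments and the requested
  correlations, not higher moments or tail dependence; the real cohort's
  joint distribution is unknown.
* Quantities derived from unrounded patient-level means in the source
  study (the 18,177 euros/QALY cost-utility ratio, the 88.14% reduction,
  the published PSA probabilities) are reproduced only to the precision
  the printed summaries allow; the package always reports ratios
  computed from its own inputs.
* The 1-year horizon means no discounting and no extrapolation of
  treatment effect; the package is not a decision-analytic model for
  lifetime horizons.
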