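---
title: "Measuring and decomposing wealth-related inequality in maternal care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing wealth-related inequality in maternal care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concindex)
```

## The model

The package measures how unevenly a binary health-care indicator is
distributed across the wealth spectrum of a survey population, and
attributes that unevenness to observed covariates.

**Outcomes.** Three indicators of maternal-care utilisation for a woman's
last birth, recoded deterministically from raw survey fields:

* *full ANC* — at least 4 antenatal visits AND at least 1 tetanus
  injection AND at least 100 IFA tablets/syrup days;
* *SBA* — delivery in a medical institution OR at home attended by a
  skilled provider (doctor/nurse/LHV/ANM);
* *PNC* — a maternal check-up at a facility/doctor within 48 hours of
  delivery.

All indicators apply to births within the five years preceding the survey.
The eligibility window is half-open — `months_since_last_birth < 60` — so a
birth exactly 60 months old is excluded, the usual DHS convention for
"births in the five years preceding the survey".

**Ranking.** Each woman receives a fractional rank $R_i \in (0,1)$ in the
weighted distribution of a continuous wealth score. We use the
Lerman–Yitzhaki midpoint construction: with normalised weights
$\tilde w_i$ and records sorted by score,
$R_i = \sum_{j<i} \tilde w_j + \tilde w_i / 2$. Tied scores share the
weighted midpoint of their whole tied block, which makes every downstream
quantity invariant to the ordering of records within a tie. The weighted
mean of $R$ is exactly $1/2$ by construction.

**The concentration index.** For an outcome with weighted mean $\mu > 0$,

$$C \;=\; \frac{2}{\mu}\,\mathrm{cov}_w(y, R),$$

with the *population* form of the weighted covariance
(divide by the weight total, not by an $n-1$ analogue). $C>0$ means the
outcome is concentrated among the better-off. $C$ also equals twice the
area between the concentration curve — cumulative weighted outcome share
against cumulative weighted population share, poorest to richest — and the
diagonal. The package computes that area by exact trapezoid integration of
the piecewise-linear curve (`ci_from_curve()`) and keeps it as an
*independent oracle*: for distinct scores the two routes agree to
$10^{-10}$ or better, and this equivalence is property-tested over random
instances.

**The decomposition.** Fitting $y_i = \alpha + \sum_k \beta_k x_{ki} +
\varepsilon_i$ on dummy-coded covariates gives the exact identity

$$C \;=\; \sum_k \Big(\frac{\beta_k \bar x_k}{\mu}\Big) C_k \;+\;
\frac{GC_\varepsilon}{\mu},$$

where $C_k$ is the concentration index of dummy $x_k$ computed with the
**same** ranks and weights as $C$ (this sameness is what makes the identity
exact — the package never mixes ranking bases within one decomposition),
$\beta_k \bar x_k/\mu$ is the elasticity, and $GC_\varepsilon =
2\,\mathrm{cov}_w(\varepsilon, R)$ the generalised concentration index of
the residual. A covariate can contribute only if it is both associated
with the outcome ($\beta_k \ne 0$) and unequally distributed over wealth
($C_k \ne 0$); a regressor with $C_k = 0$ contributes exactly zero no
matter how strong its effect.

## Design choices made where the design was open

**Regression engine.** The default is the weighted linear probability
model (`model_kind = "lpm"`), because it makes the identity above hold to
machine precision — `explained + residual = total` is asserted before any
table is written. The alternative engine (`"logit_ame"`) fits a weighted
maximum-likelihood logit and uses finite-difference average marginal
effects: for each dummy, the weighted mean of
$\hat p(x_k \leftarrow 1) - \hat p(x_k \leftarrow 0)$ holding other
regressors at their observed values. With a nonlinear engine the identity
no longer holds by construction, so the residual is *defined* as
`total - explained` and the output labels which engine produced it.
Published decomposition tables of this kind are often headed "marginal
effect" without naming the regression family; offering both engines, with
the exact-identity one as default, covers both readings.

**Ranking basis.** `ranking_basis = "continuous_score"` (default) ranks on
the continuous wealth score; `"quintile_groups"` first collapses the score
into weighted quintiles, every member of a quintile sharing one midpoint
rank. Quintile-based ranking is sometimes the stated method for the index
even when the continuous score drives the decomposition; the pipeline
computes both and reports the alternative whenever the two differ by more
than 0.005. The continuous score itself is only ever the *ranking*
variable, never a regressor: contributions are computed for the listed
covariates exactly as decomposition tables tabulate them.

**Reference categories.** Dummies follow the conventional reference set:
rural residence, age 15–24, first birth, no education, "Others" caste, no
media exposure — overridable per variable via `reference_levels`. Constant
or collinear dummy columns are dropped with a message rather than failing
the run (remaining collinearity is an error naming the columns).

**Percentage contributions.** The denominator is configurable
(`"total"`, the default, or `"explained"`) and recorded in the output,
since published percentage-contribution figures rarely state which was
used.

**Empty cells.** Gap tables report an empty poor or non-poor stratum as
`NA`, never 0: a printed 0.0 can be genuine zero utilisation, and the two
must stay distinguishable.

**Small strata.** State-wise indices recompute ranks *within* each state
(each state's own wealth ranking) and skip states with fewer than
`min_group_n = 250` records, a conventional floor below which a state-level
survey estimate of an index in $[-1,1]$ is too unstable to print.

**No standard errors.** The package deliberately reports no standard
errors or significance stars on indices, coefficients or contributions:
with complex multistage survey data an honest variance estimate needs the
design information (clusters, strata), which the flat microdata model does
not carry. Approximate influence-function standard errors are used
internally only to calibrate "statistical zero" in the recovery
diagnostics.

## The synthetic-data generator

`generate_population()` emulates the structure of NFHS-style woman-level
microdata so that every stage of the pipeline is exercised without any
restricted-access download: 14 state strata with fixed shares, lognormal
relative sampling weights (`weight_dispersion` = 0.3 by default; 0 gives
exact agreement of weighted and unweighted estimates), a continuous normal
wealth score with weighted quintile labels, six categorical covariates, and
the three outcomes.

Covariate–wealth dependence acts on the *fractional rank* of the wealth
score through logistic shifts (category probabilities proportional to
`base_probs * exp(rank_slopes * (rank - 1/2))`), not on the raw score, so
a planted covariate's concentration index does not depend on the score's
distribution. Outcomes are drawn from logistic models on the covariate
dummies plus a direct slope on the centred rank. Raw fields are then
sampled *consistently with the drawn indicator* — a full-ANC user gets
$\ge 4$ visits, $\ge 1$ tetanus dose and $\ge 100$ IFA; a non-user fails at
least one criterion — so the recode functions remain on the real execution
path and the generated table always passes `validate_survey()` with zero
rejections.

Two presets encode plausible survey-round conditions: `"nfhs3_like"`
(full ANC ≈ 9%, SBA ≈ 39%, PNC ≈ 33%) and `"nfhs4_like"` (≈ 17%, ≈ 75%,
≈ 55%), both with pro-rich gradients in education, urban residence and
media exposure, and more schooling/urbanisation/media in the later round.
The intercepts were calibrated once by large-sample simulation to those
coverage levels; exact calibration to any real survey is not claimed.

What the generator does **not** emulate: cluster/PSU design effects and
nonresponse, the asset-PCA construction of the wealth score, item
missingness patterns, and state-level heterogeneity in covariate effects.
Passing tests on synthetic data therefore demonstrate the *estimators'*
correctness (identities, closed forms, recovery of planted structure), not
that any real population satisfies the generator's assumptions.

```{r recovery}
rec <- recover_planted_structure(planted_education_scenario(5000, 1),
                                 seed = 42)
c(total = rec$total, education_share = rec$education_share)
```

When only education drives the outcome and only education is correlated
with wealth, the education rows capture essentially all of the explained
index — the joint validation of ranks, index and decomposition.

## Numerical choices and degenerate inputs

* Weighted covariances use the population form throughout; this is what
  makes `explained + residual - total` vanish to ~1e-16 rather than 1e-10.
* $\mu = 0$ (no one uses the service) leaves index, curve and
  decomposition undefined — an error, not a silent 0.
* Fewer than five distinct wealth scores make the quintile split
  degenerate: a warning, with tied blocks kept in one quintile
  (all-identical scores collapse into quintile 1).
* Perfect separation in the logit triggers a warning and a fall-back to
  the linear probability model.
* Curve endpoints are pinned to (1, 1) against floating-point drift in the
  cumulative sums; the area oracle validates anchoring and monotonicity
  before integrating.
* Problem sizes: unit and property tests run at $n \le 1000$; identity and
  recovery diagnostics use $n = 20{,}000$, where the approximate
  Monte-Carlo standard error of a null index is about 0.004, small enough
  that a planted gradient of 0.06 is unambiguous.

## Limitations

* The plain (uncorrected) index is used for binary outcomes; its
  attainable range shrinks with $\mu$ (the bound $|C| \le 1 - \mu + 1/n$
  is property-tested). Erreygers/Wagstaff normalisations for bounded
  outcomes are intentionally out of scope.
* No dominance tests between concentration curves, no Oaxaca-style
  decomposition of the *change* in inequality between rounds, no
  probit engine.
* Listwise deletion is the only missing-data strategy (with per-column
  counts logged); no imputation.
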