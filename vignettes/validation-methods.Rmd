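---
title: "Validating a nested patient-experience questionnaire: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a nested patient-experience questionnaire: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqival)
```

# The measurement problem

The CQI Inpatient Hospital Care questionnaire measures patients'
experiences with nine subscales (34 items; seven subscales on 1–4 Likert
scales, two — *admission* and *information at discharge* — on yes/no
scales), two 0–10 global ratings, and demographic covariates.
Respondents are nested in clinical departments, which are nested in
hospitals, and group sizes are unequal: the design is an *unbalanced
nested* design, `p:d` when the department is the object of measurement
and `p:d:h` when the hospital is.

Validation at two levels asks: (i) does the nine-factor structure fit
individual responses, and does it survive aggregation to the department;
(ii) are subscales internally consistent and mutually distinct; (iii) do
subscale scores predict patients' global ratings; and (iv) how much of
the score variance lies between departments and hospitals, and hence how
many respondents and departments are needed before mean scores are
precise enough to act on. `cqival` implements all four stages plus a
simulator that makes each stage testable against known truth.

# The synthetic-data model

`simulate_survey()` draws, for respondent $p$ in department $d$ of
hospital $h$ and subscale $j$,

$$z_{pdj} = \mu_j + a_{hj} + b_{dj} + e_{pj}, \qquad
a_{hj}\sim N(0,\sigma^2_{h,j}),\;
b_{dj}\sim N(0,\sigma^2_{d,j}),$$

where the respondent residual vector $e_p$ is multivariate normal with
per-subscale variances $\sigma^2_{p,j}$ and a 9×9 correlation matrix
$R$. Each item's latent response is
$\lambda\,\tilde z + \sqrt{1-\lambda^2}\,\varepsilon$ with
$\tilde z$ the standardized subscale latent, discretized by three
increasing thresholds (four categories) or one threshold (binary).
Global ratings are a clamped, rounded linear combination of the
standardized latents plus $N(0, 1)$ noise. Hospital and department
effects are independent across subscales (no published cross-level
correlation structure exists to emulate; the assumption is configurable
only by replacing the generator).

**Default configuration (the study conditions).** 23 hospitals, 22
departments per hospital (about 500 department evaluations), department
sizes drawn uniformly on 25–65 (mean ≈ 45 respondents, matching a
22 924-respondent, 515-department sample), variance components from
`cqi_reference_components()` (department plus hospital shares of total
variance ≤ 5% throughout), the published individual-level inter-subscale
correlations, loadings $\lambda = 0.8$, and thresholds calibrated so
four-point subscale means sit near 3.4 (3.0 for *own contribution* and
*communication about medication*) and binary yes-rates near 0.6
(*admission*) and 0.7 (*discharge*). Covariate category probabilities
follow the published respondent demographics. The admission-gate
question is answered "no"/blank with probability 0.02, and the default
injected item missingness is MCAR at 5% — a realistic rate for this
instrument class; no published value exists.

**What the simulator does not emulate.** Mode effects (online vs mail),
non-response behaviour, department-level correlation structure beyond
what aggregation of the individual model induces, and — importantly —
the *observed-score* variance components: the published components are
used to parameterize the **latent** subscale scores, and discretization
changes the variance scale of observed item means. Parameter-recovery
tests therefore compare Henderson estimates against the latent ground
truth stored with each dataset, and passing them shows the estimators
work, not that observed simulated scores reproduce the published
component values.

# Exclusions, imputation, pooling

A questionnaire is excluded when the admission-gate answer is negative
or missing, or when fewer than half the 34 core items are completed
(gate checked first, so the two exclusion counts are disjoint; exactly
half completed is retained — the rule is a strict "less than half").
The 34 subscale items are taken as the core-item set: they are the items
that feed every analysis, and the instrument's remaining experience
items are not enumerated anywhere usable. Both the set and the fraction
are configurable in `cqi_item_map()`.

`impute_survey()` is chained-equations imputation with type-1
predictive mean matching and 5 donors for every variable: donor values
keep imputations inside each item's observed category set without
per-item model choices. Working regressions use the variable's subscale
co-items plus the covariates (global ratings use all items), with a
Bayesian parameter draw (normal–inverse-χ²) before matching. The visit
order is ascending missingness fraction. Default 20 cycles; if any
per-variable potential scale reduction factor across the $m$ chains
exceeds 1.1, cycling continues up to the ceiling of 200 iterations and
then warns rather than fails — convergence trouble should be visible,
not fatal. `rhat()` returns 1 for identical constant chains (the 0/0
convention). Scalar estimates are pooled with Rubin's rules
(`rubin_pool()`); Cronbach's α values are instead *averaged* across
imputations, matching how reliability coefficients are conventionally
pooled for this instrument, and CFA χ² statistics are averaged before
index computation (SEM software does not publish its pooling rule for
mean-and-variance-adjusted statistics; averaging the statistic and N is
the transparent choice).

# Ordinal confirmatory factor analysis

Item-level analysis treats each ordinal item as a discretized latent
normal variable. `estimate_polychoric()` uses the two-step estimator:
thresholds from the marginal cumulative proportions, then a
one-dimensional likelihood search for $\rho$ on $(-0.999, 0.999)$. The
bivariate normal rectangle probabilities are computed by Gauss–Legendre
quadrature of $\int_{-\infty}^{a}\phi(x)\,\Phi\!\big((b-\rho
x)/\sqrt{1-\rho^2}\big)\,dx$ (48 nodes, accurate to ~1e-10); the test
suite cross-checks both the CDF (against the correlation-integral
identity) and the maximizer (against a brute-force likelihood grid).

`fit_cfa()` minimizes the diagonally weighted least-squares discrepancy
$F(\theta)=\sum_{i<j} w_{ij}(r_{ij}-\sigma_{ij}(\theta))^2$ over a
simple-structure model $\Sigma = \Lambda\Phi\Lambda'$ (factor variances
fixed at 1, 34 loadings + 36 factor correlations free, df = 491).
Weights are the reciprocal of the root-N-scaled asymptotic variance
approximation, $w_{ij} = 1/(1-\hat\rho_{ij}^2)^2$, and the test
statistic is $\chi^2 = (N-1)F_{min}$. This is deliberately **not** the
mean-and-variance-adjusted (WLSMV) statistic: the adjustment needs the
full asymptotic covariance matrix of the polychoric estimates, which is
out of scope here. What is preserved exactly is the decision layer —
CFI, TLI, RMSEA and the two-of-three rule (good: all of CFI ≥ 0.95,
TLI ≥ 0.95, RMSEA ≤ 0.06; acceptable: exactly two; poor otherwise) —
so verdicts are comparable even though raw χ² values are not.

Numerical choices: BFGS with analytic gradients from loadings 0.7 and
factor correlations 0.3; convergence requires the maximum absolute
gradient below $10^{-6}\cdot\max(1, F)$ — the scale factor matters for
ill-conditioned unit-weight problems (for example department-level fits
with few departments, where $F$ is of order 10–100 and an absolute
$10^{-6}$ bound sits below attainable double-precision resolution); the
optimizer is restarted (Hessian reset) up to five times before a
non-convergence error. Heywood-style solutions are repaired after
optimization (loadings clamped to $[-0.999, 0.999]$, factor correlation
matrix projected to the nearest correlation matrix), with warnings that
the pipeline collects into its provenance log. A non-positive-definite
polychoric matrix is repaired by eigenvalue flooring and rescaling.

Department-level CFA (`department_level_cfa()`) aggregates item means
per department (averaged across imputations), treats them as continuous
and fits with unit weights, $N$ = number of departments. Subgroup CFA
(`cfa_by_group()`) skips groups below 200 respondents by default:
polychoric matrices on 34 items become unstable well above that size,
and smaller specialties cannot support a 70-parameter model.

# Generalizability analysis

`vc_nested_2level()` and `vc_nested_3level()` implement Henderson's
analogous-ANOVA estimators, the classical method for unbalanced nested
designs (the reference analyses for this instrument were run in SPSS
VARCOMP, whose ANOVA-family default this mirrors; REML via `lme4` is
used in the test suite only as an independent cross-check). Sums of
squares are formed per stratum and equated to their expectations, with
unbalance entering through the size-dependent coefficients; on balanced
designs the estimators reduce exactly to textbook nested ANOVA.
Negative solutions are truncated to zero *after* solving the full
system (the untruncated department estimate enters the hospital
equation), keeping the estimators unbiased before truncation; every
truncation is flagged.

D-study projections use
$SEM_{dept} = \sqrt{\sigma^2_{res}/n_p}$,
$SEM_{hosp} = \sqrt{\sigma^2_d/n_d + \sigma^2_{res}/(n_d n_p)}$ and the
G coefficients $\sigma^2_{obj}/(\sigma^2_{obj} + SEM^2)$. "Reliable
enough" is operationalized as an SEM bound, not a G cutoff: the bounds
SEM < 0.10 (1–4 scales) and SEM < 0.025 (0–1 scales) correspond to
admissible 95%-band widths of $2 \times 1.96 \times SEM \approx$ 0.4
and 0.1 score units (`admissible_noise()`), and they reproduce the
published binary-subscale answers exactly. `min_respondents()` searches
multiples of 50 (sample sizes for this instrument are planned in such
steps); `min_departments()` searches integers. The package reports
*per-subscale* minima; they need not agree with blanket narrative
ranges quoted for groups of subscales (e.g. *communication about
medication*, with residual variance 0.805, needs 100 respondents under
the SEM < 0.10 rule even though 50 suffice for every other four-point
subscale).

```{r}
dstudy_grid(cqi_reference_components())$minima
```

# Construct validity

`fit_global_rating_model()` fits OLS of a global rating on the nine
subscale scores plus dummy-coded covariates (first observed level as
reference — no published reference levels exist) in each imputed
dataset, pools with Rubin's rules, and flags significance at P ≤ .05
and P ≤ .001 from the pooled t distribution. Covariate cells still
missing at analysis time are listwise-deleted within each imputed
dataset.

# Problem sizes and limitations

The test suite exercises the pipeline at reduced but structurally
faithful sizes — for example, parameter recovery uses 500 departments ×
200 respondents (two-level) and 25 hospitals × 500 departments
(three-level); CFA recovery uses N = 5000; imputation coverage uses 50
replications of a 240-respondent sample with m = 5 — sizes at which the
stated tolerances (±15–20% component recovery, ±0.05 loadings, ≥ 90%
interval coverage) are comfortably met by the estimators' sampling
theory. Known limitations: no multilevel CFA (aggregation discards
within-department variability, and a poor department-level fit can
reflect that rather than a wrong structure), no measurement-invariance
testing across specialties, no WLSMV-adjusted test statistic, no
crossed-facet or multivariate generalizability designs, and the
approximation $\widehat{Var}(\hat\rho) \approx (1-\hat\rho^2)^2/N$ in
place of exact asymptotic polychoric variances.
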