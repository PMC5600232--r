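# cqival

Two-level validation toolkit for the **CQI Inpatient Hospital Care**
questionnaire — the Dutch, HCAHPS-derived instrument measuring patients'
experiences of hospital admission. The package is aimed at survey
methodologists and hospital-quality researchers who need to answer two
questions about such an instrument: *does its nine-subscale structure hold
up* (internal validity, reliability), and *how many patients and
departments must be sampled before department- or hospital-level mean
scores are trustworthy* (generalizability).

The instrument has 34 experience items in nine subscales — *admission*
(10 yes/no items), *communication with nurses* (3), *communication with
doctors* (2), *own contribution* (5), *explanation of treatment* (3),
*pain management* (2), *communication about medication* (2), *feeling of
safety* (3) on 1–4 Likert scales, and *information at discharge* (4
yes/no) — plus two 0–10 global ratings and demographic covariates.
Respondents are nested in departments nested in hospitals.

## What the package does

* **Simulation** — `simulate_survey()` draws hierarchical ordinal data
  from a known model: latent subscale scores
  `z = μ_j + a_h + b_d + e_p` with configurable variance components
  `(σ²_h, σ²_d, σ²_p)`, a 9×9 respondent-level correlation matrix,
  item discretization through thresholds, global ratings driven by the
  latents, and MCAR/MAR missingness (`inject_missingness()`). The exact
  ground truth is returned with every dataset.
* **Screening** — `apply_exclusions()` drops questionnaires with a
  negative/missing admission-gate answer or less than half of the core
  items completed; `response_rate_summary()` does the response-rate
  arithmetic.
* **Multiple imputation** — `impute_survey()` is chained equations with
  predictive mean matching (5 donors), per-variable convergence
  monitored by the potential scale reduction factor (`rhat()`), and
  `rubin_pool()` implements Rubin's rules
  `T = W̄ + (1 + 1/m)B`.
* **Scoring and reliability** — `score_subscales()` (item means),
  `cronbach_alpha()` with the α ≥ 0.70 screen, inter-scale Pearson
  correlations with the r ≥ 0.70 overlap flag, at both the individual
  and the department-aggregated level (`reliability_report()`).
* **Ordinal CFA** — `estimate_polychoric()` (two-step ML, thresholds
  from marginals + likelihood search for ρ), `fit_cfa()` (diagonally
  weighted least squares on the polychoric matrix,
  `χ² = (N−1)·F_min`), `fit_indices()` for CFI/TLI/RMSEA, and
  `evaluate_fit()` implementing the two-of-three acceptance rule
  (CFI ≥ 0.95, TLI ≥ 0.95, RMSEA ≤ 0.06). Per-specialty runs
  (`cfa_by_group()`) and continuous CFA on department aggregates
  (`department_level_cfa()`).
* **Generalizability** — Henderson (analogous-ANOVA) variance components
  for the unbalanced nested designs `p:d` (`vc_nested_2level()`) and
  `p:d:h` (`vc_nested_3level()`), pooled across imputations; D-study
  projections `SEM_dept = √(σ²_res/n_p)`,
  `SEM_hosp = √(σ²_d/n_d + σ²_res/(n_d·n_p))`, G coefficients, and the
  minimum-sample solvers `min_respondents()` (grid of 50) and
  `min_departments()` (integer grid) against the SEM < 0.10 (1–4
  scales) and SEM < 0.025 (0–1 scales) thresholds.
* **Construct validity** — `fit_global_rating_model()` regresses a
  global rating on the nine subscale scores with covariate adjustment,
  pooled by Rubin's rules.
* **Pipeline** — `run_pipeline()` chains all stages deterministically
  and writes a JSON + text report.

## Worked example

```r
library(cqival)

comp <- cqi_reference_components()   # published variance components
comp[comp$subscale == "admission", ]
#>   subscale   kind sigma2_res sigma2_dept sigma2_hosp
#> 1 admission binary      0.059       0.003           0

# How many respondents before a department's admission score is precise?
sem_department(comp[1, ], n_p = 100)          # 0.02429...  (< 0.025)
min_respondents(comp[1, ], threshold = 0.025) # 100

# How many departments before a hospital's discharge score is precise?
dis <- comp[comp$subscale == "information_discharge", ]
min_departments(dis, n_p = 100, threshold = 0.025)  # 10

dstudy_grid(comp)$minima
#>                  subscale       kind sem_threshold min_respondents n_p_assumed min_departments
#>                 admission     binary         0.025             100         100               6
#>      communication_nurses four_point         0.100              50          50               2
#>     communication_doctors four_point         0.100              50          50               2
#>          own_contribution four_point         0.100              50          50               3
#>     explanation_treatment four_point         0.100              50          50               3
#>           pain_management four_point         0.100              50          50               2
#>  communication_medication four_point         0.100             100          50               3
#>            feeling_safety four_point         0.100              50          50               2
#>     information_discharge     binary         0.025             150         100              10
```

Reading: with residual variance 0.059, the standard error of a
department's mean admission score over 100 respondents is 0.0243, just
under the 0.025 bound implied by an admissible noise band of 0.1 on a
0–1 scale (`admissible_noise(0.025)`), so 100 respondents suffice —
while the noisier discharge subscale needs 150, and 10 departments of
100 respondents bring the hospital-level SEM under the same bound.
Most 1–4 subscales are reliable with 50 respondents per department;
*communication about medication* (residual 0.805) is the exception.

An end-to-end run on simulated data:

```r
report <- run_pipeline(pipeline_config(
  generator = sim_config(seed = 42), m = 10, seed = 42,
  out_dir = "out"))
print(report)
```

## Package layout

```
R/                  implementation (survey model, simulator, imputation,
                    scales, polychoric + CFA, G-theory, validity, pipeline)
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
vignettes/          methods vignette (model, assumptions, design choices)
```
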