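#' Published variance components for the CQI Inpatient Hospital Care subscales
#'
#' Variance component estimates from the national two-level validation of
#' the CQI Inpatient Hospital Care questionnaire (23 Dutch hospitals, 515
#' department evaluations, 22 924 respondents): residual (respondent)
#' variance, between-department variance and between-hospital variance of
#' each subscale score, estimated under the unbalanced nested
#' patients-in-departments-in-hospitals design.  These are the canonical
#' inputs for D-study planning with this instrument.
#'
#' @return A data frame with columns `subscale`, `kind` (`"four_point"` or
#'   `"binary"`), `sigma2_res`, `sigma2_dept`, `sigma2_hosp`.
#' @examples
#' vc <- cqi_reference_components()
#' variance_shares(vc[vc$subscale == "admission", ])
#' @export
cqi_reference_components <- function() {
  data.frame(
    subscale = c("admission", "communication_nurses", "communication_doctors",
                 "own_contribution", "explanation_treatment",
                 "pain_management", "communication_medication",
                 "feeling_safety", "information_discharge"),
    kind = c("binary", "four_point", "four_point", "four_point", "four_point",
             "four_point", "four_point", "four_point", "binary"),
    sigma2_res  = c(0.059, 0.360, 0.490, 0.404, 0.435, 0.376, 0.805, 0.446, 0.089),
    sigma2_dept = c(0.003, 0.005, 0.006, 0.014, 0.012, 0.008, 0.012, 0.010, 0.005),
    sigma2_hosp = c(0.000, 0.004, 0.004, 0.020, 0.003, 0.002, 0.008, 0.002, 0.000),
    stringsAsFactors = FALSE
  )
}

# Individual-level inter-subscale correlations reported for the instrument
# (upper triangle, row-wise, subscale order as in cqi_reference_components).
.cqi_reference_correlations <- function() {
  R <- diag(9)
  ut <- c(0.30, 0.29, 0.31, 0.39, 0.25, 0.38, 0.35, 0.42,
          0.56, 0.49, 0.51, 0.55, 0.47, 0.46, 0.35,
          0.42, 0.56, 0.41, 0.43, 0.37, 0.33,
          0.44, 0.38, 0.46, 0.39, 0.31,
          0.45, 0.57, 0.43, 0.43,
          0.42, 0.41, 0.32,
          0.47, 0.45,
          0.38)
  R[lower.tri(R)] <- ut        # fills row-wise in the upper triangle
  R <- R + t(R) - diag(9)
  nm <- cqi_reference_components()$subscale
  dimnames(R) <- list(nm, nm)
  R
}

# Covariate category probabilities matching the published respondent
# demographics (proportions renormalized over non-missing categories).
.cqi_covariate_probs <- function() {
  list(
    age_band = c("16-24" = 0.021, "25-34" = 0.069, "35-44" = 0.080,
                 "45-54" = 0.133, "55-64" = 0.226, "65-74" = 0.238,
                 "75-79" = 0.111, "80+" = 0.122),
    sex = c(male = 0.479, female = 0.521),
    education = c(lower_secondary = 0.286, upper_secondary = 0.459,
                  tertiary = 0.255),
    physical_health = c(excellent = 0.061, very_good = 0.219, good = 0.466,
                        average = 0.292, bad = 0.053),
    psych_health = c(excellent = 0.181, very_good = 0.238, good = 0.478,
                     average = 0.093, bad = 0.009),
    origin = c(netherlands = 0.923, germany = 0.007, antilles = 0.013,
               indonesia = 0.012, morocco_turkey = 0.008, other = 0.032),
    n_admissions = c("1" = 0.579, "2" = 0.259, "3" = 0.092, "4+" = 0.064)
  )
}
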