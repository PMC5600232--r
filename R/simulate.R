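#' Configuration for the hierarchical survey simulator
#'
#' Defines the generative model for synthetic CQI-style data: patients
#' nested in departments nested in hospitals, a correlated nine-subscale
#' latent structure discretized to ordinal items, global ratings driven by
#' the subscale latents, demographic covariates, and (optionally, via
#' [inject_missingness()]) item-level missingness.
#'
#' The latent subscale score of respondent *p* in department *d* of
#' hospital *h* on subscale *j* is
#' \deqn{z_{pdj} = \mu_j + a_{hj} + b_{dj} + e_{pj}}
#' with \eqn{a_{hj} \sim N(0, \sigma^2_{h,j})},
#' \eqn{b_{dj} \sim N(0, \sigma^2_{d,j})} and the respondent residual
#' vector \eqn{e_p} drawn multivariate normal with inter-subscale
#' correlation `R` and per-subscale variance \eqn{\sigma^2_{p,j}}.  Each
#' item's latent response is \eqn{\lambda \tilde z + \sqrt{1-\lambda^2}\,
#' \epsilon} where \eqn{\tilde z} is the standardized subscale latent,
#' discretized by the thresholds `tau` (four categories) or `tau_b`
#' (binary).  Global ratings are a clamped, rounded linear combination
#' `beta_sim` of the standardized subscale latents plus noise.
#'
#' Defaults reproduce the published study conditions for this instrument:
#' 23 hospitals, 22 departments per hospital (roughly 515 department
#' evaluations), department sizes drawn uniformly from 25--65 respondents,
#' the published variance components ([cqi_reference_components()]) and
#' individual-level inter-subscale correlations, loadings of 0.8, and
#' thresholds calibrated to the published subscale means (about 3.4--3.5
#' for most four-point subscales, 3.0 for *own contribution* and
#' *communication about medication*; yes-rates 0.6 and 0.7 for the two
#' binary subscales).
#'
#' @param n_hospitals Number of hospitals.
#' @param departments_per_hospital Integer, or integer vector of length
#'   `n_hospitals`.
#' @param respondents_per_department Single integer for balanced designs,
#'   or a length-2 vector `c(min, max)` for a discrete-uniform unbalanced
#'   design.
#' @param components Data frame with columns `subscale`, `kind`,
#'   `sigma2_res`, `sigma2_dept`, `sigma2_hosp` (one row per subscale).
#' @param mu Latent subscale means (length 9).
#' @param R 9x9 respondent-level inter-subscale correlation matrix.
#' @param lambda Item loading on its subscale latent, scalar in `[-1, 1]`.
#' @param tau Named list of four-point thresholds (length-3 increasing
#'   vectors) per subscale; `tau_b` named numeric of binary thresholds.
#' @param tau_b See `tau`.
#' @param beta_sim Coefficients linking standardized subscale latents to
#'   the global ratings (length 9).
#' @param rating_intercept,rating_sd Intercept and noise SD of the global
#'   ratings.
#' @param gate_no_rate Probability that the admission-gate question is
#'   answered "no" or left blank.
#' @param covariate_probs Named list of category probabilities.
#' @param specialty_probs Named probabilities used to label departments.
#' @param seed Integer root seed; all streams derive from it.
#' @return A list of class `cqi_sim_config`.
#' @seealso [simulate_survey()]
#' @export
sim_config <- function(n_hospitals = 23,
                       departments_per_hospital = 22,
                       respondents_per_department = c(25, 65),
                       components = cqi_reference_components(),
                       mu = c(0.6, 3.4, 3.4, 3.0, 3.5, 3.5, 3.0, 3.4, 0.7),
                       R = .cqi_reference_correlations(),
                       lambda = 0.8,
                       tau = NULL,
                       tau_b = NULL,
                       beta_sim = c(admission = 0.15,
                                    communication_nurses = 1.00,
                                    communication_doctors = 0.10,
                                    own_contribution = 0.30,
                                    explanation_treatment = 0.05,
                                    pain_management = 0.35,
                                    communication_medication = 0.00,
                                    feeling_safety = 0.20,
                                    information_discharge = 0.55),
                       rating_intercept = 7.5,
                       rating_sd = 1.0,
                       gate_no_rate = 0.02,
                       covariate_probs = .cqi_covariate_probs(),
                       specialty_probs = c(surgery = 0.45,
                                           cardiology = 0.20,
                                           internal_medicine = 0.25,
                                           obstetrics_gynaecology = 0.10),
                       seed = 1L) {
  stopifnot(is.data.frame(components),
            all(c("subscale", "kind", "sigma2_res", "sigma2_dept",
                  "sigma2_hosp") %in% names(components)))
  J <- nrow(components)
  if (any(components$sigma2_res < 0) || any(components$sigma2_dept < 0) ||
      any(components$sigma2_hosp < 0))
    stop("variance components must be non-negative", call. = FALSE)
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-8))
    stop("R must be symmetric with unit diagonal", call. = FALSE)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("inter-subscale correlation matrix R is not positive semi-definite",
         call. = FALSE)
  if (abs(lambda) > 1) stop("|lambda| must be <= 1", call. = FALSE)
  stopifnot(length(mu) == J, length(beta_sim) == J)

  # Threshold defaults: a high-mean regime (~3.4 on 1-4) and a lower one
  # (~3.0); binary yes-rates 0.6 (admission-like) and 0.7 (discharge-like).
  tau_hi <- c(-1.6, -1.0, -0.35)
  tau_lo <- c(-1.3, -0.55, 0.10)
  if (is.null(tau)) {
    tau <- lapply(seq_len(J), function(j) {
      if (components$kind[j] != "four_point") return(NULL)
      if (mu[j] <= 3.2) tau_lo else tau_hi
    })
    names(tau) <- components$subscale
  }
  if (is.null(tau_b)) {
    tau_b <- vapply(seq_len(J), function(j) {
      if (components$kind[j] != "binary") return(NA_real_)
      qnorm(1 - min(max(mu[j], 0.05), 0.95))
    }, numeric(1))
    names(tau_b) <- components$subscale
  }
  for (j in seq_len(J)) {
    if (components$kind[j] == "four_point" &&
        any(diff(tau[[components$subscale[j]]]) <= 0))
      stop("four-point thresholds must be strictly increasing", call. = FALSE)
  }

  structure(list(n_hospitals = n_hospitals,
                 departments_per_hospital = departments_per_hospital,
                 respondents_per_department = respondents_per_department,
                 components = components, mu = mu, R = R, lambda = lambda,
                 tau = tau, tau_b = tau_b, beta_sim = beta_sim,
                 rating_intercept = rating_intercept, rating_sd = rating_sd,
                 gate_no_rate = gate_no_rate,
                 covariate_probs = covariate_probs,
                 specialty_probs = specialty_probs,
                 seed = as.integer(seed)),
            class = "cqi_sim_config")
}

#' Generate a synthetic hierarchical survey
#'
#' Draws a complete respondent-level dataset from the model described in
#' [sim_config()] and returns it together with the exact ground truth used
#' (variance components, correlations, loadings, thresholds, rating
#' coefficients, and every respondent's latent subscale scores), so that
#' downstream estimators can be checked against known parameters.
#' Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (a `cqi_survey`) and `truth`
#'   (list holding the generating parameters and the n x 9 latent score
#'   matrix plus per-hospital/per-department effects).
#' @examples
#' sim <- simulate_survey(sim_config(n_hospitals = 2,
#'   departments_per_hospital = 3, respondents_per_department = 10,
#'   seed = 42))
#' dim(sim$dataset)
#' @export
simulate_survey <- function(config = sim_config()) {
  stopifnot(inherits(config, "cqi_sim_config"))
  set.seed(config$seed)
  comp <- config$components
  J <- nrow(comp)
  H <- config$n_hospitals

  b_per_h <- config$departments_per_hospital
  if (length(b_per_h) == 1L) b_per_h <- rep(b_per_h, H)
  stopifnot(length(b_per_h) == H)
  n_dept <- sum(b_per_h)

  rpd <- config$respondents_per_department
  dept_sizes <- if (length(rpd) == 1L) rep(rpd, n_dept) else
    sample(seq(rpd[1], rpd[2]), n_dept, replace = TRUE)
  N <- sum(dept_sizes)

  hosp_of_dept <- rep(seq_len(H), b_per_h)
  dept_ids <- paste0("H", sprintf("%02d", hosp_of_dept), "_D",
                     unlist(lapply(b_per_h, seq_len)))
  hosp_id <- rep(paste0("H", sprintf("%02d", hosp_of_dept)), dept_sizes)
  dept_id <- rep(dept_ids, dept_sizes)
  specialty <- rep(sample(names(config$specialty_probs), n_dept,
                          replace = TRUE, prob = config$specialty_probs),
                   dept_sizes)

  # latent subscale scores: hospital + department effects, correlated
  # respondent residuals
  sd_h <- sqrt(comp$sigma2_hosp); sd_d <- sqrt(comp$sigma2_dept)
  sd_p <- sqrt(comp$sigma2_res)
  a_h <- matrix(rnorm(H * J), H, J) %*% diag(sd_h, J)
  b_d <- matrix(rnorm(n_dept * J), n_dept, J) %*% diag(sd_d, J)
  L <- chol(config$R)
  e <- matrix(rnorm(N * J), N, J) %*% L %*% diag(sd_p, J)
  h_idx <- rep(hosp_of_dept, dept_sizes)
  d_idx <- rep(seq_len(n_dept), dept_sizes)
  z <- sweep(a_h[h_idx, , drop = FALSE] + b_d[d_idx, , drop = FALSE] + e,
             2, config$mu, `+`)
  tot_sd <- sqrt(comp$sigma2_hosp + comp$sigma2_dept + comp$sigma2_res)
  z_std <- sweep(sweep(z, 2, config$mu, `-`), 2, tot_sd, `/`)
  colnames(z) <- colnames(z_std) <- comp$subscale

  # discretized items
  lam <- config$lambda
  d <- data.frame(respondent_id = seq_len(N), hospital_id = hosp_id,
                  department_id = dept_id, specialty = specialty,
                  stringsAsFactors = FALSE)
  for (j in seq_len(J)) {
    sname <- comp$subscale[j]
    its <- .cqi_items_for(sname)
    for (it in its) {
      ystar <- lam * z_std[, j] + sqrt(1 - lam^2) * rnorm(N)
      d[[it]] <- if (comp$kind[j] == "four_point") {
        as.numeric(cut(ystar, c(-Inf, config$tau[[sname]], Inf),
                       labels = FALSE))
      } else {
        as.numeric(ystar > config$tau_b[[sname]])
      }
    }
  }

  # admission gate, global ratings, covariates
  d$admitted_12m <- rbinom(N, 1, 1 - config$gate_no_rate)
  lin <- as.vector(z_std %*% config$beta_sim)
  clamp10 <- function(x) pmin(10, pmax(0, round(x)))
  d$dept_rating <- clamp10(config$rating_intercept + lin +
                             rnorm(N, sd = config$rating_sd))
  d$hosp_rating <- clamp10(config$rating_intercept + 0.8 * lin +
                             rnorm(N, sd = config$rating_sd))
  for (cv in names(config$covariate_probs)) {
    p <- config$covariate_probs[[cv]]
    d[[cv]] <- sample(names(p), N, replace = TRUE, prob = p)
  }

  truth <- list(components = comp, R = config$R, lambda = lam,
                tau = config$tau, tau_b = config$tau_b,
                beta_sim = config$beta_sim, mu = config$mu,
                latent_scores = z, hospital_effects = a_h,
                department_effects = b_d, seed = config$seed)
  ds <- survey_dataset(d, cqi_item_map(),
                       provenance = list(generator = "simulate_survey",
                                         seed = config$seed))
  list(dataset = ds, truth = truth)
}

# default map lookup used by the generator
.cqi_items_for <- function(subscale) {
  .cqi_default_subscales()[[subscale]]$items
}

#' Inject item-level missingness
#'
#' Blanks item cells either completely at random (MCAR) or at a rate that
#' depends on a covariate's category (MAR): under MAR each respondent's
#' cell-missingness probability is `rate * w / mean(w)` where `w` is the
#' respondent's category weight, so the overall rate stays at `rate`.
#'
#' @param ds A `cqi_survey`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate Target missingness rate in `[0, 1)`.
#' @param seed Integer seed.
#' @param covariate Covariate column driving MAR (default `"age_band"`).
#' @param weights Named non-negative weights per category of `covariate`;
#'   default doubles the rate in the last category.
#' @return The dataset with missing item cells.
#' @export
inject_missingness <- function(ds, mechanism = c("MCAR", "MAR"), rate,
                               seed = 1L, covariate = "age_band",
                               weights = NULL) {
  stopifnot(inherits(ds, "cqi_survey"))
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(ds)
  set.seed(as.integer(seed))
  d <- ds$data
  items <- intersect(map_items(ds$item_map), names(d))
  n <- nrow(d)

  p_row <- if (mechanism == "MCAR") {
    rep(rate, n)
  } else {
    if (!covariate %in% names(d))
      stop("MAR covariate not in data: ", covariate, call. = FALSE)
    cats <- d[[covariate]]
    lev <- unique(cats)
    if (is.null(weights)) {
      weights <- setNames(rep(1, length(lev)), lev)
      weights[length(weights)] <- 2
    }
    if (!all(cats %in% names(weights)))
      stop("weights missing for some categories of ", covariate,
           call. = FALSE)
    w <- unname(weights[cats])
    pmin(0.95, rate * w / mean(w))
  }
  for (it in items) {
    hit <- runif(n) < p_row
    d[[it]][hit] <- NA_real_
  }
  survey_dataset(d, ds$item_map,
                 provenance = c(ds$provenance,
                                list(missingness = list(mechanism = mechanism,
                                                        rate = rate,
                                                        seed = seed))))
}
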