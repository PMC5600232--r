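#' Variance components for the unbalanced single-facet nested design (p:d)
#'
#' Henderson (analogous-ANOVA) estimation for respondents nested in
#' departments with unequal group sizes.  With `N` respondents in `k`
#' departments of sizes \eqn{n_d}:
#' \deqn{MS_w = \sum_d\sum_p (y - \bar y_d)^2 / (N - k), \qquad
#'       MS_b = \sum_d n_d (\bar y_d - \bar y)^2 / (k - 1)}
#' \deqn{c = \Big(N - \sum_d n_d^2 / N\Big) / (k - 1)}
#' \eqn{\hat\sigma^2_{res} = MS_w} and \eqn{\hat\sigma^2_d = \max(0,
#' (MS_b - MS_w)/c)}; a negative department component is truncated to zero
#' and flagged.  On balanced designs `c` equals the common group size and
#' the estimator reduces to classical nested ANOVA.
#'
#' @param y Numeric vector of scores (one per respondent).
#' @param department Department label per respondent.
#' @return List of class `cqi_vc`: `sigma2_dept`, `sigma2_res`,
#'   `sigma2_hosp` (NA), `design = "p:d"`, `truncated`, `ms_within`,
#'   `ms_between`, `c_coef`, `n_groups`, `n_total`.
#' @examples
#' vc_nested_2level(c(1, 2, 3, 3, 4), c("A", "A", "A", "B", "B"))
#' @export
vc_nested_2level <- function(y, department) {
  ok <- !is.na(y) & !is.na(department)
  y <- y[ok]; department <- as.character(department)[ok]
  N <- length(y)
  sizes <- table(department)
  k <- length(sizes)
  if (k < 2L) stop("need at least 2 departments", call. = FALSE)
  if (N - k <= 0)
    stop("all departments are singletons: residual variance inestimable",
         call. = FALSE)
  gm <- tapply(y, department, mean)
  grand <- mean(y)
  ss_w <- sum((y - gm[department])^2)
  ms_w <- ss_w / (N - k)
  ms_b <- sum(sizes * (gm - grand)^2) / (k - 1)
  c_coef <- (N - sum(sizes^2) / N) / (k - 1)
  raw_d <- (ms_b - ms_w) / c_coef
  truncated <- raw_d < 0
  structure(list(sigma2_dept = max(0, raw_d), sigma2_res = ms_w,
                 sigma2_hosp = NA_real_, design = "p:d",
                 truncated = truncated, ms_within = ms_w, ms_between = ms_b,
                 c_coef = c_coef, n_groups = k, n_total = N),
            class = "cqi_vc")
}

#' Variance components for the multifacet unbalanced nested design (p:d:h)
#'
#' Henderson estimation for respondents nested in departments nested in
#' hospitals.  Sums of squares are formed at the hospital,
#' department-within-hospital, and residual strata; expected-mean-square
#' coefficients follow from the group sizes (hospital `i`, department `j`
#' within it, sizes \eqn{n_{ij}}, hospital totals \eqn{n_{i.}}, `a`
#' hospitals, \eqn{\sum b_i} departments, `N` respondents):
#' \deqn{k_1 = \frac{N - \sum_{ij} n_{ij}^2/n_{i.}}{\sum b_i - a}, \quad
#'       k_2 = \frac{\sum_{ij} n_{ij}^2/n_{i.} - \sum_{ij} n_{ij}^2/N}{a-1},
#'       \quad
#'       k_3 = \frac{N - \sum_i n_{i.}^2/N}{a - 1}}
#' The system \eqn{E[MS_{res}] = \sigma^2_{res}}, \eqn{E[MS_d] =
#' \sigma^2_{res} + k_1\sigma^2_d}, \eqn{E[MS_h] = \sigma^2_{res} +
#' k_2\sigma^2_d + k_3\sigma^2_h} is solved bottom-up; negative solutions
#' are truncated to zero after solving (the untruncated department
#' estimate enters the hospital equation, keeping the solution unbiased
#' before truncation).  On balanced designs \eqn{k_1 = k_2 = n} and
#' \eqn{k_3 = bn}, the classical nested-ANOVA coefficients.
#'
#' @param y Numeric score per respondent.
#' @param department,hospital Labels per respondent; department labels
#'   need not be unique across hospitals.
#' @return List of class `cqi_vc` with `sigma2_hosp`, `sigma2_dept`,
#'   `sigma2_res`, `design = "p:d:h"`, `truncated` (named logical),
#'   and the mean squares and k-coefficients.
#' @export
vc_nested_3level <- function(y, department, hospital) {
  ok <- !is.na(y) & !is.na(department) & !is.na(hospital)
  y <- y[ok]
  hosp <- as.character(hospital)[ok]
  dept <- paste(hosp, as.character(department)[ok], sep = "\r")
  N <- length(y)
  a <- length(unique(hosp))
  if (a < 2L) stop("need at least 2 hospitals", call. = FALSE)
  n_ij <- table(dept)
  n_i <- table(hosp)
  b_tot <- length(n_ij)
  if (b_tot - a <= 0)
    stop("degenerate department stratum: no departments beyond hospitals",
         call. = FALSE)
  if (N - b_tot <= 0)
    stop("degenerate residual stratum: no replication within departments",
         call. = FALSE)
  hosp_of_dept <- sub("\r.*$", "", names(n_ij))

  m_d <- tapply(y, dept, mean)
  m_h <- tapply(y, hosp, mean)
  grand <- mean(y)
  ss_res <- sum((y - m_d[dept])^2)
  ss_d <- sum(n_ij * (m_d - m_h[hosp_of_dept])^2)
  ss_h <- sum(n_i * (m_h - grand)^2)
  ms_res <- ss_res / (N - b_tot)
  ms_d <- ss_d / (b_tot - a)
  ms_h <- ss_h / (a - 1)

  sum_nij2_ni <- sum(n_ij^2 / n_i[hosp_of_dept])
  k1 <- (N - sum_nij2_ni) / (b_tot - a)
  k2 <- (sum_nij2_ni - sum(n_ij^2) / N) / (a - 1)
  k3 <- (N - sum(n_i^2) / N) / (a - 1)

  raw_res <- ms_res
  raw_d <- (ms_d - raw_res) / k1
  raw_h <- (ms_h - raw_res - k2 * raw_d) / k3
  truncated <- c(dept = raw_d < 0, hosp = raw_h < 0)
  structure(list(sigma2_hosp = max(0, raw_h), sigma2_dept = max(0, raw_d),
                 sigma2_res = raw_res, design = "p:d:h",
                 truncated = truncated,
                 ms = c(res = ms_res, dept = ms_d, hosp = ms_h),
                 k = c(k1 = k1, k2 = k2, k3 = k3),
                 n_hospitals = a, n_departments = b_tot, n_total = N),
            class = "cqi_vc")
}

#' @export
print.cqi_vc <- function(x, ...) {
  cat("<cqi_vc>", x$design, "design:")
  if (!is.na(x$sigma2_hosp)) cat(" hospital", signif(x$sigma2_hosp, 3))
  cat(" department", signif(x$sigma2_dept, 3),
      "residual", signif(x$sigma2_res, 3), "\n")
  if (any(unlist(x$truncated))) cat("  (negative component(s) truncated to 0)\n")
  invisible(x)
}

#' Average variance components across imputations
#'
#' Arithmetic mean per component; variance shares and the
#' hospital/(hospital + department) ratio are recomputed from the pooled
#' values via [variance_shares()].
#'
#' @param vcs List of `cqi_vc` objects from the same design.
#' @return A `cqi_vc` with pooled components and a `shares` field.
#' @export
pool_components <- function(vcs) {
  stopifnot(length(vcs) >= 1L, all(vapply(vcs, inherits, logical(1), "cqi_vc")))
  designs <- unique(vapply(vcs, `[[`, character(1), "design"))
  if (length(designs) != 1L) stop("mixed designs cannot be pooled",
                                  call. = FALSE)
  get <- function(f) mean(vapply(vcs, function(v) v[[f]], numeric(1)))
  pooled <- list(sigma2_hosp = get("sigma2_hosp"),
                 sigma2_dept = get("sigma2_dept"),
                 sigma2_res = get("sigma2_res"),
                 design = designs,
                 truncated = any(unlist(lapply(vcs, `[[`, "truncated"))),
                 m = length(vcs))
  pooled$shares <- variance_shares(pooled)
  class(pooled) <- "cqi_vc"
  pooled
}

#' Variance shares and hospital-dominance ratio
#'
#' Percentage of total score variance attributable to the department and
#' the hospital (rounded to whole percents, the convention for reporting
#' these designs), and the ratio \eqn{\sigma^2_h / (\sigma^2_h +
#' \sigma^2_d)} expressing how much of the group-level variance sits at
#' the hospital (0 when both components are zero).
#'
#' @param components A `cqi_vc`, a one-row data frame, or a named list
#'   with `sigma2_res`, `sigma2_dept` and (optionally) `sigma2_hosp`.
#' @return List with `share_dept_pct`, `share_hosp_pct` (integers),
#'   `ratio_hosp` (rounded to 2 decimals), `total`.
#' @examples
#' variance_shares(list(sigma2_res = 0.059, sigma2_dept = 0.003,
#'                      sigma2_hosp = 0))
#' @export
variance_shares <- function(components) {
  cmp <- .vc_values(components)
  total <- cmp[["res"]] + cmp[["dept"]] + cmp[["hosp"]]
  if (total <= 0) stop("total variance must be positive", call. = FALSE)
  denom <- cmp[["hosp"]] + cmp[["dept"]]
  list(share_dept_pct = round(100 * cmp[["dept"]] / total),
       share_hosp_pct = round(100 * cmp[["hosp"]] / total),
       ratio_hosp = if (denom == 0) 0 else round(cmp[["hosp"]] / denom, 2),
       total = total)
}

# normalize the various component containers to c(res=, dept=, hosp=)
.vc_values <- function(components) {
  if (is.data.frame(components)) components <- as.list(components[1, ])
  res <- components$sigma2_res
  dept <- components$sigma2_dept
  hosp <- components$sigma2_hosp
  if (is.null(hosp) || is.na(hosp)) hosp <- 0
  if (is.null(dept) || is.na(dept)) dept <- 0
  stopifnot(!is.null(res))
  c(res = res, dept = dept, hosp = hosp)
}

#' Standard error of measurement of a department mean
#'
#' For a department mean over `n_p` respondents,
#' \eqn{SEM = \sqrt{\sigma^2_{res} / n_p}}.
#'
#' @param components Component container (see [variance_shares()]).
#' @param n_p Respondents per department.
#' @return SEM (same units as the score).
#' @examples
#' sem_department(list(sigma2_res = 0.059), n_p = 100)
#' @export
sem_department <- function(components, n_p) {
  cmp <- .vc_values(components)
  stopifnot(n_p > 0)
  sqrt(cmp[["res"]] / n_p)
}

#' Standard error of measurement of a hospital mean
#'
#' For a hospital mean over `n_d` departments with `n_p` respondents each,
#' \eqn{SEM = \sqrt{\sigma^2_d / n_d + \sigma^2_{res} / (n_d n_p)}}.
#'
#' @inheritParams sem_department
#' @param n_d Departments per hospital.
#' @export
sem_hospital <- function(components, n_d, n_p) {
  cmp <- .vc_values(components)
  stopifnot(n_d > 0, n_p > 0)
  sqrt(cmp[["dept"]] / n_d + cmp[["res"]] / (n_d * n_p))
}

#' Generalizability (G) coefficient
#'
#' Department level (`n_d = NULL`): \eqn{\sigma^2_d / (\sigma^2_d +
#' \sigma^2_{res}/n_p)}.  Hospital level: \eqn{\sigma^2_h / (\sigma^2_h +
#' \sigma^2_d/n_d + \sigma^2_{res}/(n_d n_p))}.
#'
#' @inheritParams sem_hospital
#' @param n_d Departments per hospital; `NULL` for the department-level
#'   coefficient.
#' @return Value in `[0, 1)`.
#' @export
g_coefficient <- function(components, n_p, n_d = NULL) {
  cmp <- .vc_values(components)
  if (is.null(n_d)) {
    obj <- cmp[["dept"]]
    err <- cmp[["res"]] / n_p
  } else {
    obj <- cmp[["hosp"]]
    err <- cmp[["dept"]] / n_d + cmp[["res"]] / (n_d * n_p)
  }
  if (obj == 0 && err == 0) return(0)
  obj / (obj + err)
}

#' Admissible-noise bound implied by an SEM threshold
#'
#' The half-width convention for interpreting a 95% confidence band around
#' a mean score: a SEM threshold `s` corresponds to an admissible noise
#' band of `2 * 1.96 * s` score units (e.g. 0.4 units on a 1--4 scale for
#' SEM < 0.10, and 0.1 on a 0--1 scale for SEM < 0.025).
#'
#' @param sem_threshold SEM threshold.
#' @return Width of the 95% band.
#' @examples
#' admissible_noise(0.10)   # ~0.4
#' admissible_noise(0.025)  # ~0.1
#' @export
admissible_noise <- function(sem_threshold) {
  stopifnot(sem_threshold > 0)
  2 * 1.96 * sem_threshold
}

#' Minimum respondents per department for a target SEM
#'
#' Smallest multiple of `grid_step` respondents for which the
#' department-level SEM falls strictly below `threshold`.
#'
#' @inheritParams sem_department
#' @param threshold SEM threshold (> 0), e.g. 0.10 for four-point scales
#'   or 0.025 for binary scales.
#' @param grid_step Respondent grid step (default 50).
#' @param max_n Search ceiling.
#' @return Number of respondents.
#' @examples
#' min_respondents(list(sigma2_res = 0.059), threshold = 0.025)  # 100
#' @export
min_respondents <- function(components, threshold, grid_step = 50,
                            max_n = 1e6) {
  stopifnot(threshold > 0, grid_step >= 1)
  cmp <- .vc_values(components)
  if (cmp[["res"]] <= 0) stop("residual variance must be positive",
                              call. = FALSE)
  n <- grid_step
  while (n <= max_n) {
    if (sem_department(components, n) < threshold) return(n)
    n <- n + grid_step
  }
  stop("no grid point below threshold up to ", max_n, call. = FALSE)
}

#' Minimum departments per hospital for a target SEM
#'
#' Smallest integer number of departments (each with `n_p` respondents)
#' for which the hospital-level SEM falls strictly below `threshold`.
#'
#' @inheritParams sem_hospital
#' @param threshold SEM threshold (> 0).
#' @param max_n Search ceiling.
#' @return Number of departments.
#' @examples
#' min_departments(list(sigma2_dept = 0.005, sigma2_res = 0.089,
#'                      sigma2_hosp = 0), n_p = 100, threshold = 0.025)  # 10
#' @export
min_departments <- function(components, n_p, threshold, max_n = 1e6) {
  stopifnot(threshold > 0, n_p > 0)
  n_d <- 1
  while (n_d <= max_n) {
    if (sem_hospital(components, n_d, n_p) < threshold) return(n_d)
    n_d <- n_d + 1
  }
  stop("no department count below threshold up to ", max_n, call. = FALSE)
}

#' D-study: SEM and G-coefficient surfaces with minimum-sample solutions
#'
#' Projects measurement precision under hypothetical designs: for each
#' subscale, the department-level SEM and G coefficient over a grid of
#' respondents-per-department, the hospital-level SEM and G over the full
#' (respondents x departments) grid, and the minimum samples needed to
#' push the SEM below the scale-appropriate threshold (0.10 for
#' four-point subscales, 0.025 for binary, by default).
#'
#' @param components Data frame with columns `subscale`, `kind`,
#'   `sigma2_res`, `sigma2_dept`, `sigma2_hosp` (e.g.
#'   [cqi_reference_components()]), or a single `cqi_vc`.
#' @param n_p_grid Respondents-per-department grid.
#' @param n_d_grid Departments-per-hospital grid.
#' @param thresholds Named SEM thresholds per scale kind.
#' @param n_p_for_departments Respondents per department assumed when
#'   solving for the minimum number of departments (default 100 for
#'   binary subscales, 50 for four-point, mirroring the department-level
#'   minima conventions; a single number overrides both).
#' @return Object of class `cqi_dstudy`: `surface` (long data frame of
#'   grid points) and `minima` (per subscale: `min_respondents`,
#'   `min_departments`, thresholds used).
#' @examples
#' ds <- dstudy_grid(cqi_reference_components())
#' ds$minima
#' @export
dstudy_grid <- function(components,
                        n_p_grid = seq(50, 300, by = 50),
                        n_d_grid = 1:20,
                        thresholds = c(four_point = 0.10, binary = 0.025),
                        n_p_for_departments = NULL) {
  if (inherits(components, "cqi_vc"))
    components <- data.frame(subscale = "score", kind = "four_point",
                             sigma2_res = components$sigma2_res,
                             sigma2_dept = components$sigma2_dept,
                             sigma2_hosp = if (is.na(components$sigma2_hosp)) 0
                                           else components$sigma2_hosp)
  stopifnot(is.data.frame(components))
  surface <- NULL
  minima <- NULL
  for (r in seq_len(nrow(components))) {
    cmp <- components[r, ]
    thr <- thresholds[[cmp$kind]]
    dep <- data.frame(subscale = cmp$subscale, level = "department",
                      n_p = n_p_grid, n_d = NA_integer_,
                      sem = vapply(n_p_grid, function(np)
                        sem_department(cmp, np), numeric(1)),
                      g = vapply(n_p_grid, function(np)
                        g_coefficient(cmp, np), numeric(1)))
    hg <- expand.grid(n_p = n_p_grid, n_d = n_d_grid)
    hos <- data.frame(subscale = cmp$subscale, level = "hospital",
                      n_p = hg$n_p, n_d = hg$n_d,
                      sem = mapply(function(np, nd)
                        sem_hospital(cmp, nd, np), hg$n_p, hg$n_d),
                      g = mapply(function(np, nd)
                        g_coefficient(cmp, np, nd), hg$n_p, hg$n_d))
    surface <- rbind(surface, dep, hos)
    np_dept <- if (!is.null(n_p_for_departments)) n_p_for_departments
               else if (cmp$kind == "binary") 100 else 50
    minima <- rbind(minima, data.frame(
      subscale = cmp$subscale, kind = cmp$kind, sem_threshold = thr,
      min_respondents = min_respondents(cmp, thr,
                                        grid_step = min(diff(unique(n_p_grid)),
                                                        50)),
      n_p_assumed = np_dept,
      min_departments = min_departments(cmp, np_dept, thr)))
  }
  # monotonicity invariants of the projection
  for (s in unique(surface$subscale)) {
    dep <- surface[surface$subscale == s & surface$level == "department", ]
    stopifnot(all(diff(dep$sem[order(dep$n_p)]) < 0),
              all(diff(dep$g[order(dep$n_p)]) >= 0))
  }
  structure(list(surface = surface, minima = minima,
                 thresholds = thresholds),
            class = "cqi_dstudy")
}

#' @export
print.cqi_dstudy <- function(x, ...) {
  cat("<cqi_dstudy>\n")
  print(x$minima, row.names = FALSE)
  invisible(x)
}
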