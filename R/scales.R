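#' Subscale scores per respondent
#'
#' The score on a subscale is the arithmetic mean of its available item
#' codes, so four-point subscales score in `[1, 4]` and binary subscales
#' in `[0, 1]`.  On incomplete data a respondent's subscale score is
#' computed when at least half of the subscale's items are observed and is
#' missing otherwise; on completed (post-imputation) data all scores are
#' defined.
#'
#' @param ds A `cqi_survey`.
#' @return Data frame with `respondent_id`, `hospital_id`,
#'   `department_id`, `specialty`, and one score column per subscale.
#' @examples
#' sim <- simulate_survey(sim_config(n_hospitals = 2,
#'   departments_per_hospital = 2, respondents_per_department = 10,
#'   seed = 1))
#' head(score_subscales(sim$dataset))
#' @export
score_subscales <- function(ds) {
  stopifnot(inherits(ds, "cqi_survey"))
  d <- ds$data
  out <- d[intersect(c("respondent_id", "hospital_id", "department_id",
                       "specialty"), names(d))]
  for (nm in names(ds$item_map$subscales)) {
    its <- intersect(ds$item_map$subscales[[nm]]$items, names(d))
    mat <- as.matrix(d[its])
    n_obs <- rowSums(!is.na(mat))
    sc <- rowMeans(mat, na.rm = TRUE)
    sc[n_obs < length(its) / 2] <- NA_real_
    out[[nm]] <- sc
  }
  out
}

#' Aggregate respondent-level variables to the department level
#'
#' Unweighted mean over the respondents of each department, for every
#' numeric column (items, subscale scores, or ratings).
#'
#' @param x A `cqi_survey` or a data frame carrying `hospital_id` and
#'   `department_id` columns (e.g. the output of [score_subscales()]).
#' @param columns Columns to aggregate; defaults to all numeric columns
#'   except the identifiers.
#' @return Data frame, one row per (hospital, department), with an
#'   `n_respondents` column.
#' @export
aggregate_to_department <- function(x, columns = NULL) {
  d <- if (inherits(x, "cqi_survey")) x$data else x
  stopifnot(all(c("hospital_id", "department_id") %in% names(d)))
  if (is.null(columns))
    columns <- setdiff(names(d)[vapply(d, is.numeric, logical(1))],
                       c("respondent_id"))
  key <- interaction(d$hospital_id, d$department_id, drop = TRUE)
  agg <- aggregate(d[columns], by = list(key = key),
                   FUN = function(v) mean(v, na.rm = TRUE))
  ids <- d[!duplicated(key), c("hospital_id", "department_id")]
  ids <- ids[match(levels(key), key[!duplicated(key)]), ]
  out <- cbind(ids, n_respondents = as.vector(table(key)[levels(key)]),
               agg[setdiff(names(agg), "key")])
  rownames(out) <- NULL
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \deqn{\alpha = \frac{k}{k-1}\Big(1 - \frac{\sum_i s_i^2}{s_{tot}^2}\Big)}
#' with `k` items, per-item sample variances \eqn{s_i^2} and the variance
#' of the row totals \eqn{s_{tot}^2}.
#'
#' @param item_matrix Numeric matrix or data frame, respondents x items
#'   (>= 2 items, >= 2 complete rows).  Rows with missing values are
#'   dropped.
#' @return Scalar alpha.
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' cronbach_alpha(x + rnorm(100))  # shared row effect -> positive alpha
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  x <- x[complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2L) stop("need at least 2 items", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 complete rows", call. = FALSE)
  s_tot <- var(rowSums(x))
  if (s_tot == 0) stop("zero total-score variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / s_tot)
}

#' Inter-scale correlations and overlap flags
#'
#' Pearson correlations between subscale scores; off-diagonal values of
#' at least 0.70 are flagged as substantially overlapping (i.e. the two
#' subscales may not measure distinct constructs).
#'
#' @param scores Data frame of subscale scores (individual- or
#'   department-level); non-score columns are ignored.
#' @param subscales Character vector of score column names; defaults to
#'   the nine default subscale names present in `scores`.
#' @param overlap_cutoff Flagging threshold (default 0.70).
#' @return List with `correlations` (symmetric matrix) and `overlap`
#'   (data frame of flagged pairs, possibly empty).
#' @export
interscale_correlations <- function(scores,
                                    subscales = NULL,
                                    overlap_cutoff = 0.70) {
  if (is.null(subscales))
    subscales <- intersect(names(.cqi_default_subscales()), names(scores))
  if (length(subscales) < 2L) stop("need at least 2 subscales", call. = FALSE)
  x <- as.matrix(scores[subscales])
  if (sum(complete.cases(x)) < 3L)
    stop("need at least 3 complete rows", call. = FALSE)
  R <- cor(x, use = "pairwise.complete.obs")
  flag <- which(abs(R) >= overlap_cutoff & upper.tri(R), arr.ind = TRUE)
  overlap <- data.frame(subscale_1 = rownames(R)[flag[, 1]],
                        subscale_2 = colnames(R)[flag[, 2]],
                        r = R[flag], stringsAsFactors = FALSE)
  list(correlations = R, overlap = overlap)
}

#' Reliability and overlap screen across imputations
#'
#' For each imputed dataset, computes Cronbach's alpha per subscale at the
#' individual level (respondent x item matrix) and at the department level
#' (per-item department means), and the inter-scale correlation matrices
#' at both levels.  Alphas and correlations are pooled by simple averaging
#' across imputations.  A subscale is acceptable when its pooled alpha is
#' at least `alpha_cutoff`; score pairs correlating at or above
#' `overlap_cutoff` are flagged as overlapping.
#'
#' @param imps A `cqi_imputation` (or a single completed `cqi_survey`).
#' @param alpha_cutoff Acceptance threshold for alpha (default 0.70).
#' @param overlap_cutoff Overlap threshold for inter-scale correlations.
#' @return List of class `cqi_reliability` with per-subscale alpha tables
#'   (`alpha`, columns `individual`/`department`/acceptance flags) and
#'   per-level correlation matrices plus flagged pairs.
#' @export
reliability_report <- function(imps, alpha_cutoff = 0.70,
                               overlap_cutoff = 0.70) {
  datasets <- if (inherits(imps, "cqi_imputation")) imps$datasets
              else list(imps)
  map <- datasets[[1]]$item_map
  subs <- names(map$subscales)

  alpha_i <- alpha_d <- matrix(NA_real_, length(datasets), length(subs),
                               dimnames = list(NULL, subs))
  cor_i <- cor_d <- 0
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    dept_items <- aggregate_to_department(ds, columns =
      intersect(map_items(map), names(ds$data)))
    for (s in subs) {
      its <- intersect(map$subscales[[s]]$items, names(ds$data))
      alpha_i[i, s] <- cronbach_alpha(ds$data[its])
      alpha_d[i, s] <- cronbach_alpha(dept_items[its])
    }
    sc_i <- score_subscales(ds)
    sc_d <- aggregate_to_department(sc_i, columns = subs)
    cor_i <- cor_i + interscale_correlations(sc_i)$correlations
    cor_d <- cor_d + interscale_correlations(sc_d)$correlations
  }
  m <- length(datasets)
  cor_i <- cor_i / m; cor_d <- cor_d / m
  flag_pairs <- function(R) {
    idx <- which(abs(R) >= overlap_cutoff & upper.tri(R), arr.ind = TRUE)
    data.frame(subscale_1 = rownames(R)[idx[, 1]],
               subscale_2 = colnames(R)[idx[, 2]], r = R[idx],
               stringsAsFactors = FALSE)
  }
  alpha <- data.frame(subscale = subs,
                      individual = colMeans(alpha_i),
                      department = colMeans(alpha_d))
  alpha$acceptable_individual <- alpha$individual >= alpha_cutoff
  alpha$acceptable_department <- alpha$department >= alpha_cutoff
  rownames(alpha) <- NULL
  structure(list(alpha = alpha,
                 correlations = list(individual = cor_i, department = cor_d),
                 overlap = list(individual = flag_pairs(cor_i),
                                department = flag_pairs(cor_d)),
                 alpha_cutoff = alpha_cutoff,
                 overlap_cutoff = overlap_cutoff, m = m),
            class = "cqi_reliability")
}

#' @export
print.cqi_reliability <- function(x, ...) {
  cat("<cqi_reliability> pooled over", x$m, "imputation(s)\n")
  print(transform(x$alpha, individual = round(individual, 2),
                  department = round(department, 2)))
  n_ov <- nrow(x$overlap$department)
  cat(if (n_ov > 0) paste(n_ov, "overlapping pair(s) at department level\n")
      else "no overlapping pairs at department level\n")
  invisible(x)
}
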