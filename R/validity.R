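#' Construct-validity regression of a global rating on subscale scores
#'
#' Ordinary least squares of a 0--10 global rating (department or
#' hospital) on the nine subscale scores, adjusted for the demographic
#' covariates (dummy-coded, first observed level as reference), fitted in
#' every imputed dataset and pooled with Rubin's rules ([rubin_pool()]).
#' Confidence intervals use the pooled total variance and Rubin degrees
#' of freedom; significance flags follow the `P <= .05` (`*`) and
#' `P <= .001` (`**`) convention.
#'
#' @param imps A `cqi_imputation` (or single completed `cqi_survey`; a
#'   single dataset is fitted without pooling).
#' @param outcome `"dept_rating"` or `"hosp_rating"` (any rating column).
#' @param covariates Covariate columns to adjust for; defaults to the
#'   item map's covariate fields present in the data.
#' @return Data frame of class `cqi_regression`: one row per term with
#'   `estimate`, `se`, `ci_lo`, `ci_hi`, `df`, `p`, `sig`; attributes
#'   `outcome`, `m`, `N`.
#' @examples
#' sim <- simulate_survey(sim_config(n_hospitals = 3,
#'   departments_per_hospital = 3, respondents_per_department = 40,
#'   seed = 8))
#' fit_global_rating_model(sim$dataset, outcome = "dept_rating")
#' @export
fit_global_rating_model <- function(imps, outcome = "dept_rating",
                                    covariates = NULL) {
  datasets <- if (inherits(imps, "cqi_imputation")) imps$datasets
              else list(imps)
  map <- datasets[[1]]$item_map
  subs <- names(map$subscales)
  if (is.null(covariates))
    covariates <- intersect(map$covariate_fields, names(datasets[[1]]$data))

  fits <- lapply(datasets, function(ds) {
    sc <- score_subscales(ds)
    d <- cbind(sc[subs], ds$data[c(outcome, covariates)])
    for (cv in covariates) d[[cv]] <- factor(d[[cv]])
    d <- d[complete.cases(d), , drop = FALSE]
    f <- as.formula(paste(outcome, "~",
                          paste(c(subs, covariates), collapse = " + ")))
    fit <- lm(f, data = d)
    if (any(is.na(coef(fit))))
      stop("rank-deficient design; aliased terms: ",
           paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
           call. = FALSE)
    list(coef = coef(fit), var = diag(vcov(fit)), n = nrow(d))
  })

  terms <- names(fits[[1]]$coef)
  m <- length(fits)
  rows <- lapply(terms, function(tm) {
    Q <- vapply(fits, function(f) f$coef[[tm]], numeric(1))
    U <- vapply(fits, function(f) f$var[[tm]], numeric(1))
    if (m == 1L) {
      se <- sqrt(U)
      df <- fits[[1]]$n - length(terms)
      half <- qt(0.975, df) * se
      p <- 2 * pt(-abs(Q / se), df)
      data.frame(term = tm, estimate = Q, se = se, ci_lo = Q - half,
                 ci_hi = Q + half, df = df, p = p)
    } else {
      pl <- rubin_pool(Q, U)
      se <- sqrt(pl$t)
      p <- 2 * pt(-abs(pl$qbar / se), pl$df)
      data.frame(term = tm, estimate = pl$qbar, se = se,
                 ci_lo = pl$ci[1], ci_hi = pl$ci[2], df = pl$df, p = p)
    }
  })
  out <- do.call(rbind, rows)
  out$sig <- ifelse(out$p <= 0.001, "**", ifelse(out$p <= 0.05, "*", ""))
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  attr(out, "m") <- m
  attr(out, "N") <- fits[[1]]$n
  class(out) <- c("cqi_regression", "data.frame")
  out
}

#' @export
print.cqi_regression <- function(x, digits = 3, ...) {
  cat("construct-validity regression of", attr(x, "outcome"),
      "(m =", attr(x, "m"), ", N =", attr(x, "N"), ")\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
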