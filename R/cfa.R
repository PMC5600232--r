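#' Confirmatory factor model specification
#'
#' Simple-structure measurement model: every item loads on exactly one
#' factor, factor variances are fixed to 1, factor correlations are free,
#' and unique variances are `1 - diag(Lambda Phi Lambda')` (the model is
#' fit to a correlation matrix, so only off-diagonal elements carry
#' information).  Free parameters are the `p` loadings and the `q(q-1)/2`
#' factor correlations; model degrees of freedom are `p(p-1)/2` minus the
#' free-parameter count.
#'
#' @param item_map A [cqi_item_map()], or a named list mapping factor
#'   names to character vectors of item names.
#' @return List of class `cqi_cfa_spec` with `items`, `factor_of`
#'   (named factor index per item), `factors`, `df`, `n_free`.
#' @export
cfa_spec <- function(item_map = cqi_item_map()) {
  assign_list <- if (inherits(item_map, "cqi_item_map"))
    lapply(item_map$subscales, `[[`, "items") else item_map
  factors <- names(assign_list)
  items <- unlist(assign_list, use.names = FALSE)
  if (anyDuplicated(items))
    stop("an item loads on two factors", call. = FALSE)
  factor_of <- rep(seq_along(factors), lengths(assign_list))
  names(factor_of) <- items
  p <- length(items); q <- length(factors)
  n_free <- p + q * (q - 1) / 2
  df <- p * (p - 1) / 2 - n_free
  if (df <= 0) stop("model is not identified: non-positive degrees of freedom",
                    call. = FALSE)
  structure(list(items = items, factor_of = factor_of, factors = factors,
                 df = df, n_free = n_free),
            class = "cqi_cfa_spec")
}

# model-implied correlation matrix and its building blocks
.cfa_sigma <- function(lambda, phi, factor_of) {
  L <- matrix(0, length(lambda), nrow(phi))
  L[cbind(seq_along(lambda), factor_of)] <- lambda
  list(L = L, sigma = L %*% phi %*% t(L))
}

#' Fit a factor model to a correlation matrix by weighted least squares
#'
#' Minimizes the diagonally weighted least-squares discrepancy
#' \deqn{F(\theta) = \sum_{i<j} w_{ij}\,(r_{ij} - \sigma_{ij}(\theta))^2}
#' over the loadings and factor correlations of `spec`, where
#' \eqn{\sigma(\theta) = \Lambda\Phi\Lambda'}.  Optimization is
#' quasi-Newton (BFGS with analytic gradient) from starting values 0.7
#' (loadings) and 0.3 (factor correlations); convergence requires the
#' maximum absolute gradient below `tol`.  The test statistic is
#' \eqn{\chi^2 = (N-1)\,F_{min}} (no mean-and-variance adjustment; see the
#' package vignette for the difference from WLSMV test statistics — the
#' CFI/TLI/RMSEA decision layer is unaffected).
#'
#' Heywood-style solutions are repaired after optimization: loadings are
#' clamped to `[-0.999, 0.999]` and a non-positive-semi-definite factor
#' correlation matrix is projected to the nearest correlation matrix,
#' both with a warning.
#'
#' @param R Sample correlation matrix (polychoric or Pearson).
#' @param W Symmetric weight matrix (use `matrix(1, p, p)` for unweighted
#'   least squares on aggregated data); only off-diagonals are used.
#' @param spec A [cfa_spec()].
#' @param N Sample size behind `R`.
#' @param tol Gradient tolerance for convergence.
#' @param maxit Maximum BFGS iterations before a non-convergence error.
#' @return List of class `cqi_cfa_fit`: `loadings` (named), `phi`,
#'   `fmin`, `chisq`, `df`, `chisq_baseline`, `df_baseline`, `N`,
#'   `converged`, `heywood`.
#' @export
fit_cfa <- function(R, W = NULL, spec, N, tol = 1e-6, maxit = 500L) {
  stopifnot(inherits(spec, "cqi_cfa_spec"))
  p <- length(spec$items); q <- length(spec$factors)
  if (!all(spec$items %in% rownames(R)))
    stop("correlation matrix lacks items: ",
         paste(setdiff(spec$items, rownames(R)), collapse = ", "),
         call. = FALSE)
  R <- R[spec$items, spec$items]
  if (is.null(W)) W <- matrix(1, p, p)
  else if (!is.null(dimnames(W))) W <- W[spec$items, spec$items]
  diag(W) <- 0
  fo <- spec$factor_of
  lt <- which(lower.tri(matrix(0, q, q)), arr.ind = TRUE)

  unpack <- function(theta) {
    lambda <- theta[seq_len(p)]
    phi <- diag(q)
    phi[lt] <- theta[p + seq_len(nrow(lt))]
    phi[cbind(lt[, 2], lt[, 1])] <- phi[lt]
    list(lambda = lambda, phi = phi)
  }
  off <- upper.tri(R)
  fn <- function(theta) {
    par <- unpack(theta)
    sg <- .cfa_sigma(par$lambda, par$phi, fo)$sigma
    sum(W[off] * (R[off] - sg[off])^2)
  }
  gr <- function(theta) {
    par <- unpack(theta)
    sl <- .cfa_sigma(par$lambda, par$phi, fo)
    E <- W * (R - sl$sigma); diag(E) <- 0     # symmetric residual weight
    GL <- -2 * E %*% sl$L %*% par$phi         # d/dLambda (full matrix)
    g_lambda <- GL[cbind(seq_len(p), fo)]
    GP <- -2 * t(sl$L) %*% E %*% sl$L         # d/dPhi
    c(g_lambda, GP[lt])
  }
  theta0 <- c(rep(0.7, p), rep(0.3, nrow(lt)))
  # convergence: max gradient below tol, scaled by the magnitude of F so
  # that ill-conditioned unit-weight problems are judged on a comparable
  # footing; BFGS is restarted (Hessian reset) until the criterion holds
  opt <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-15))
  g <- gr(opt$par)
  gbound <- function() tol * max(1, abs(opt$value))
  restarts <- 0L
  while (max(abs(g)) >= gbound() && restarts < 5L) {
    restarts <- restarts + 1L
    opt <- optim(opt$par, fn, gr, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-15))
    g <- gr(opt$par)
  }
  converged <- max(abs(g)) < gbound()
  if (!converged)
    stop(sprintf("CFA did not converge in %d iterations (gradient norm %.3g)",
                 maxit, sqrt(sum(g^2))), call. = FALSE)

  par <- unpack(opt$par)
  heywood <- FALSE
  if (any(abs(par$lambda) > 0.999)) {
    heywood <- TRUE
    par$lambda <- pmin(0.999, pmax(-0.999, par$lambda))
    warning("Heywood case: loadings clamped to [-0.999, 0.999]",
            call. = FALSE)
  }
  ev <- eigen(par$phi, symmetric = TRUE)
  if (min(ev$values) < 0) {
    heywood <- TRUE
    vals <- pmax(ev$values, 1e-6)
    P2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    Dinv <- diag(1 / sqrt(diag(P2)))
    par$phi <- Dinv %*% P2 %*% Dinv
    warning("factor correlation matrix projected to nearest PSD",
            call. = FALSE)
  }
  fmin <- fn(c(par$lambda, par$phi[lt]))
  fb <- sum(W[off] * R[off]^2)                # baseline: all correlations zero
  dimnames(par$phi) <- list(spec$factors, spec$factors)
  structure(list(loadings = setNames(par$lambda, spec$items),
                 phi = par$phi, fmin = fmin,
                 chisq = (N - 1) * fmin, df = spec$df,
                 chisq_baseline = (N - 1) * fb,
                 df_baseline = p * (p - 1) / 2,
                 N = N, converged = converged, heywood = heywood),
            class = "cqi_cfa_fit")
}

#' @export
print.cqi_cfa_fit <- function(x, ...) {
  fi <- fit_indices(x$chisq, x$df, x$chisq_baseline, x$df_baseline, x$N)
  cat(sprintf("<cqi_cfa_fit> chisq = %.1f (df %d), CFI %.3f, TLI %.3f, RMSEA %.3f -> %s\n",
              x$chisq, x$df, fi$cfi, fi$tli, fi$rmsea, fi$verdict))
  invisible(x)
}

#' Goodness-of-fit indices for a factor model
#'
#' \deqn{CFI = 1 - \frac{\max(\chi^2_m - df_m, 0)}
#'   {\max(\chi^2_b - df_b,\ \chi^2_m - df_m,\ 0)}}
#' \deqn{TLI = \frac{\chi^2_b/df_b - \chi^2_m/df_m}{\chi^2_b/df_b - 1}}
#' \deqn{RMSEA = \sqrt{\frac{\max(\chi^2_m - df_m, 0)}{df_m (N-1)}}}
#' TLI is undefined when \eqn{\chi^2_b/df_b \le 1} and is reported as
#' missing with a warning.
#'
#' @param chisq_m,df_m Model test statistic and degrees of freedom.
#' @param chisq_b,df_b Baseline (independence) statistic and df.
#' @param N Sample size.
#' @param cutoffs Named vector of acceptance cutoffs
#'   (CFI >= 0.95, TLI >= 0.95, RMSEA <= 0.06 by default).
#' @return List of class `cqi_fit_indices`: `cfi`, `tli`, `rmsea`,
#'   `chisq_m`, `df_m`, `chisq_b`, `df_b`, `N`, `verdict`.
#' @examples
#' fit_indices(100, 50, 1000, 60, 1001)
#' @export
fit_indices <- function(chisq_m, df_m, chisq_b, df_b, N,
                        cutoffs = c(cfi = 0.95, tli = 0.95, rmsea = 0.06)) {
  if (df_m <= 0 || df_b <= 0) stop("degrees of freedom must be positive",
                                   call. = FALSE)
  if (N <= 1) stop("N must exceed 1", call. = FALSE)
  num <- max(chisq_m - df_m, 0)
  den <- max(chisq_b - df_b, chisq_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rb <- chisq_b / df_b
  tli <- if (rb <= 1) {
    warning("baseline chisq/df <= 1: TLI undefined", call. = FALSE)
    NA_real_
  } else (rb - chisq_m / df_m) / (rb - 1)
  rmsea <- sqrt(max(chisq_m - df_m, 0) / (df_m * (N - 1)))
  structure(list(cfi = cfi, tli = tli, rmsea = rmsea,
                 chisq_m = chisq_m, df_m = df_m,
                 chisq_b = chisq_b, df_b = df_b, N = N,
                 verdict = evaluate_fit(cfi, tli, rmsea, cutoffs)),
            class = "cqi_fit_indices")
}

#' @export
print.cqi_fit_indices <- function(x, ...) {
  cat(sprintf("CFI %.3f, TLI %s, RMSEA %.3f -> %s\n", x$cfi,
              ifelse(is.na(x$tli), "NA", sprintf("%.3f", x$tli)),
              x$rmsea, x$verdict))
  invisible(x)
}

#' Two-of-three fit acceptance rule
#'
#' Model fit is `"good"` when all three criteria are met (CFI >= 0.95,
#' TLI >= 0.95, RMSEA <= 0.06), `"acceptable"` when exactly two are met,
#' and `"poor"` otherwise.  A missing index counts as an unmet criterion.
#'
#' @param cfi,tli,rmsea Fit indices.
#' @param cutoffs Named cutoff vector, see [fit_indices()].
#' @return `"good"`, `"acceptable"` or `"poor"`.
#' @examples
#' evaluate_fit(0.96, 0.95, 0.04)   # good
#' evaluate_fit(0.83, 0.81, 0.06)   # poor
#' @export
evaluate_fit <- function(cfi, tli, rmsea,
                         cutoffs = c(cfi = 0.95, tli = 0.95, rmsea = 0.06)) {
  met <- sum(isTRUE(cfi >= cutoffs[["cfi"]]),
             isTRUE(tli >= cutoffs[["tli"]]),
             isTRUE(rmsea <= cutoffs[["rmsea"]]))
  if (met == 3) "good" else if (met == 2) "acceptable" else "poor"
}

# one ordinal CFA on a completed data frame: polychoric matrix -> DWLS fit
.cfa_once <- function(d, spec) {
  pm <- polychoric_matrix(d, items = spec$items)
  fit_cfa(pm$rho, pm$weights, spec, N = nrow(d))
}

#' Ordinal CFA per group, pooled across imputations
#'
#' Runs the ordinal (polychoric + DWLS) CFA independently in each level of
#' a grouping variable and in each imputed dataset, pools the model and
#' baseline test statistics by averaging across imputations, and computes
#' fit indices from the pooled statistics.  Groups smaller than `min_n`
#' respondents are skipped with a warning.  With `group_field = NULL` the
#' whole sample forms a single group (`"all"`).
#'
#' @param imps A `cqi_imputation` or a single completed `cqi_survey`.
#' @param group_field Grouping column (default `"specialty"`), or `NULL`.
#' @param spec A [cfa_spec()]; defaults to the dataset's item map.
#' @param min_n Minimum group size (default 200).
#' @return Named list of `cqi_fit_indices`, one per retained group.
#' @export
cfa_by_group <- function(imps, group_field = "specialty", spec = NULL,
                         min_n = 200L) {
  datasets <- if (inherits(imps, "cqi_imputation")) imps$datasets
              else list(imps)
  map <- datasets[[1]]$item_map
  if (is.null(spec)) spec <- cfa_spec(map)
  d1 <- datasets[[1]]$data
  groups <- if (is.null(group_field)) list(all = seq_len(nrow(d1)))
            else split(seq_len(nrow(d1)), d1[[group_field]])
  out <- list()
  for (g in names(groups)) {
    rows <- groups[[g]]
    if (length(rows) < min_n) {
      warning("group '", g, "' has fewer than ", min_n,
              " respondents; skipped", call. = FALSE)
      next
    }
    stats <- vapply(datasets, function(ds) {
      fit <- .cfa_once(ds$data[rows, , drop = FALSE], spec)
      c(fit$chisq, fit$chisq_baseline, fit$N)
    }, numeric(3))
    out[[g]] <- fit_indices(mean(stats[1, ]), spec$df, mean(stats[2, ]),
                            length(spec$items) * (length(spec$items) - 1) / 2,
                            mean(stats[3, ]))
  }
  out
}

#' Department-level CFA on aggregated item means
#'
#' Aggregates every item to its department mean (averaged across imputed
#' datasets when a `cqi_imputation` is supplied), treats the aggregates as
#' continuous, and fits the factor model to their Pearson correlation
#' matrix with unit weights; N is the number of departments.
#'
#' @param x A `cqi_imputation` or completed `cqi_survey`.
#' @param spec A [cfa_spec()]; defaults to the dataset's item map.
#' @return A `cqi_fit_indices`.
#' @export
department_level_cfa <- function(x, spec = NULL) {
  datasets <- if (inherits(x, "cqi_imputation")) x$datasets else list(x)
  map <- datasets[[1]]$item_map
  if (is.null(spec)) spec <- cfa_spec(map)
  items <- spec$items
  aggs <- lapply(datasets, function(ds)
    aggregate_to_department(ds, columns = intersect(items, names(ds$data))))
  agg <- aggs[[1]]
  if (length(aggs) > 1)
    for (k in 2:length(aggs)) agg[items] <- agg[items] + aggs[[k]][items]
  agg[items] <- agg[items] / length(aggs)
  n_dept <- nrow(agg)
  if (n_dept < 3L)
    stop("department-level CFA needs at least 3 departments (got ",
         n_dept, ")", call. = FALSE)
  R <- cor(as.matrix(agg[items]))
  fit <- fit_cfa(R, W = matrix(1, length(items), length(items)),
                 spec = spec, N = n_dept)
  fit_indices(fit$chisq, fit$df, fit$chisq_baseline, fit$df_baseline, n_dept)
}
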