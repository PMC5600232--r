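#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing item and global-rating cells by iterating per-variable
#' working regressions in a fixed visit order (ascending missingness
#' fraction), drawing regression parameters from their approximate
#' posterior and imputing each missing cell with the observed value of one
#' of its 5 nearest donors on the predicted metric (type-1 predictive mean
#' matching).  Because imputations are donor values, they always lie in the
#' observed category set of the variable.  `m` independent chains are run,
#' each yielding one completed dataset; per-iteration chain means of the
#' imputed values are recorded so convergence can be checked with
#' [rhat()].
#'
#' Predictors are the variable's subscale co-items plus the (numerically
#' coded) covariates; global ratings are regressed on all items plus
#' covariates.  Observed cells are never altered.
#'
#' @param ds A `cqi_survey` with missing values.
#' @param m Number of imputations (>= 2).
#' @param n_iterations Chained-equation cycles per chain (default 20).
#' @param max_iterations Ceiling on cycles; if the convergence diagnostic
#'   exceeds 1.1 after `n_iterations`, cycling continues (in steps of
#'   `n_iterations`) up to this many iterations, then warns.
#' @param seed Integer seed.
#' @param donors Number of predictive-mean-matching donors.
#' @return An object of class `cqi_imputation`: list with `datasets` (m
#'   completed `cqi_survey` objects), `chain_means` (list per imputed
#'   variable of iterations x chains matrices), `rhat` (named vector),
#'   and `settings`.
#' @examples
#' sim <- simulate_survey(sim_config(n_hospitals = 2,
#'   departments_per_hospital = 2, respondents_per_department = 15,
#'   seed = 3))
#' ds <- inject_missingness(sim$dataset, "MCAR", 0.1, seed = 4)
#' imp <- impute_survey(ds, m = 2, n_iterations = 3, seed = 5)
#' length(imp$datasets)
#' @export
impute_survey <- function(ds, m = 10, n_iterations = 20,
                          max_iterations = 200, seed = 1L, donors = 5L) {
  stopifnot(inherits(ds, "cqi_survey"))
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  d <- ds$data
  map <- ds$item_map
  items <- intersect(map_items(map), names(d))
  ratings <- intersect(map$global_rating_fields, names(d))
  targets <- c(items, ratings)

  frac_mis <- vapply(targets, function(v) mean(is.na(d[[v]])), numeric(1))
  fully_missing <- targets[frac_mis == 1]
  if (length(fully_missing) > 0L)
    stop("variable(s) 100% missing: ",
         paste(fully_missing, collapse = ", "), call. = FALSE)
  to_impute <- targets[frac_mis > 0]
  settings <- list(m = m, n_iterations = n_iterations,
                   max_iterations = max_iterations, seed = seed,
                   donors = donors, method = "pmm")

  if (length(to_impute) == 0L) {
    datasets <- replicate(m, survey_dataset(d, map, ds$provenance),
                          simplify = FALSE)
    return(structure(list(datasets = datasets, chain_means = list(),
                          rhat = numeric(0), settings = settings),
                     class = "cqi_imputation"))
  }
  # visit order: least missing first
  to_impute <- to_impute[order(frac_mis[to_impute])]

  # numeric predictor frame: items, ratings, numerically coded covariates
  covs <- intersect(map$covariate_fields, names(d))
  covs <- covs[vapply(covs, function(cv) !anyNA(d[[cv]]), logical(1))]
  cov_num <- lapply(covs, function(cv) as.numeric(factor(d[[cv]])))
  names(cov_num) <- covs
  subs_of <- map_item_subscales(map)

  predictors_of <- function(v) {
    if (v %in% items) {
      co <- setdiff(intersect(names(subs_of)[subs_of == subs_of[[v]]], items), v)
      c(co, covs)
    } else {
      c(items, covs)
    }
  }

  n <- nrow(d)
  mis_idx <- lapply(to_impute, function(v) which(is.na(d[[v]])))
  names(mis_idx) <- to_impute
  obs_idx <- lapply(mis_idx, function(ix) setdiff(seq_len(n), ix))

  build_X <- function(cur, preds) {
    cols <- c(lapply(setdiff(preds, covs), function(p) cur[[p]]),
              cov_num[intersect(preds, covs)])
    cbind(1, do.call(cbind, cols))
  }

  # initial fill per chain: random draws from the observed values
  chains <- replicate(m, {
    cur <- d
    for (v in to_impute) {
      ix <- mis_idx[[v]]
      cur[[v]][ix] <- sample(cur[[v]][obs_idx[[v]]], length(ix),
                             replace = TRUE)
    }
    cur
  }, simplify = FALSE)

  means <- lapply(to_impute, function(v)
    matrix(NA_real_, nrow = 0, ncol = m))
  names(means) <- to_impute
  iter <- 0L
  repeat {
    for (step in seq_len(n_iterations)) {
      iter <- iter + 1L
      for (ch in seq_len(m)) {
        cur <- chains[[ch]]
        for (v in to_impute) {
          X <- build_X(cur, predictors_of(v))
          cur[[v]][mis_idx[[v]]] <-
            .pmm_draw(y = d[[v]], X = X, ox = obs_idx[[v]],
                      ix = mis_idx[[v]], donors = donors)
        }
        chains[[ch]] <- cur
      }
      for (v in to_impute)
        means[[v]] <- rbind(means[[v]], vapply(chains, function(cur)
          mean(cur[[v]][mis_idx[[v]]]), numeric(1)))
      if (iter >= max_iterations) break
    }
    rh <- vapply(means, rhat, numeric(1))
    if (all(rh <= 1.1, na.rm = TRUE) || iter >= max_iterations) break
  }
  if (any(rh > 1.1, na.rm = TRUE))
    warning("imputation chains may not have converged (Rhat > 1.1 for ",
            paste(names(rh)[which(rh > 1.1)], collapse = ", "),
            ") after ", iter, " iterations (ceiling ", max_iterations, ")",
            call. = FALSE)

  chain_means <- means
  datasets <- lapply(seq_len(m), function(i)
    survey_dataset(chains[[i]], map,
                   c(ds$provenance, list(imputation = i, seed = seed))))
  structure(list(datasets = datasets, chain_means = chain_means,
                 rhat = rh, settings = settings),
            class = "cqi_imputation")
}

# One PMM update: Bayesian parameter draw, type-1 matching, donor sampling.
.pmm_draw <- function(y, X, ox, ix, donors) {
  yo <- y[ox]
  Xo <- X[ox, , drop = FALSE]
  qx <- qr(Xo)
  keep <- qx$pivot[seq_len(qx$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[ix, keep, drop = FALSE]
  qx <- qr(Xo)
  beta_hat <- qr.coef(qx, yo)
  res <- yo - as.vector(Xo %*% beta_hat)
  df <- max(length(ox) - qx$rank, 1L)
  sigma2_star <- sum(res^2) / rchisq(1, df)
  Rm <- qr.R(qx)
  beta_star <- beta_hat +
    backsolve(Rm, rnorm(ncol(Xo))) * sqrt(sigma2_star)
  yhat_obs <- as.vector(Xo %*% beta_hat)
  yhat_mis <- as.vector(Xm %*% beta_star)
  k <- min(donors, length(ox))
  vapply(yhat_mis, function(p) {
    dset <- order(abs(yhat_obs - p))[seq_len(k)]
    yo[dset[sample.int(k, 1)]]
  }, numeric(1))
}

#' @export
print.cqi_imputation <- function(x, ...) {
  cat("<cqi_imputation> m =", x$settings$m, "completed datasets;",
      length(x$chain_means), "imputed variables\n")
  if (length(x$rhat) > 0)
    cat("  max Rhat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Potential scale reduction factor
#'
#' Gelman--Rubin convergence diagnostic over parallel chains:
#' \deqn{\hat R = \sqrt{\frac{(L-1)/L \cdot W + B/L}{W}}}
#' with `W` the mean within-chain variance and `B` the between-chain
#' variance of the chain means times the chain length `L`.  When all
#' chains are identical constants (0/0), returns 1 by convention.
#'
#' @param chains Numeric matrix, iterations x chains (>= 2 chains, >= 2
#'   iterations), or a list of equal-length numeric vectors.
#' @return A scalar, approximately >= 1.
#' @examples
#' rhat(cbind(rnorm(100), rnorm(100)))
#' @export
rhat <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L) stop("chains must have equal length", call. = FALSE)
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  L <- nrow(chains); M <- ncol(chains)
  if (M < 2L) stop("need at least 2 chains", call. = FALSE)
  if (L < 2L) stop("need at least 2 iterations per chain", call. = FALSE)
  W <- mean(apply(chains, 2, var))
  B <- L * var(colMeans(chains))
  if (W == 0 && B == 0) return(1)
  if (W == 0) return(Inf)
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Combines per-imputation point estimates `Q_i` and variances `U_i`:
#' \eqn{\bar Q = m^{-1}\sum Q_i}, within-variance \eqn{\bar W = m^{-1}\sum
#' U_i}, between-variance \eqn{B} the sample variance of the `Q_i`, total
#' \eqn{T = \bar W + (1 + 1/m)B}, degrees of freedom by Rubin's
#' small-sample formula \eqn{(m-1)(1 + \bar W / ((1+1/m)B))^2}.
#'
#' @param Q Numeric vector of per-imputation estimates (length m >= 2).
#' @param U Numeric vector of per-imputation variances (same length,
#'   >= 0).
#' @param conf Confidence level for the symmetric interval.
#' @return List of class `cqi_pooled` with `qbar`, `wbar`, `b`, `t`, `df`,
#'   `ci` (length 2), `m`.
#' @examples
#' rubin_pool(c(1, 2, 3), c(1, 1, 1))
#' @export
rubin_pool <- function(Q, U, conf = 0.95) {
  m <- length(Q)
  if (m < 2L) stop("need at least 2 imputations to pool", call. = FALSE)
  if (length(U) != m) stop("Q and U must have equal length", call. = FALSE)
  if (any(U < 0)) stop("variances U must be non-negative", call. = FALSE)
  qbar <- mean(Q)
  wbar <- mean(U)
  b <- var(Q)
  t <- wbar + (1 + 1 / m) * b
  df <- if (b == 0) Inf else (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2
  half <- qt(1 - (1 - conf) / 2, df) * sqrt(t)
  structure(list(qbar = qbar, wbar = wbar, b = b, t = t, df = df,
                 ci = c(qbar - half, qbar + half), m = m),
            class = "cqi_pooled")
}

#' @export
print.cqi_pooled <- function(x, ...) {
  cat(sprintf("pooled estimate %.4g (95%% CI %.4g to %.4g), T = %.4g, df = %.3g\n",
              x$qbar, x$ci[1], x$ci[2], x$t, x$df))
  invisible(x)
}
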