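make_implied_R <- function(lam, spec, Phi) {
  L <- matrix(0, length(lam), nrow(Phi))
  L[cbind(seq_along(lam), spec$factor_of)] <- lam
  R <- L %*% Phi %*% t(L)
  diag(R) <- 1
  dimnames(R) <- list(spec$items, spec$items)
  R
}

test_that("the default model specification is identified", {
  spec <- cfa_spec()
  expect_equal(spec$n_free, 34 + 36)
  expect_equal(spec$df, 34 * 33 / 2 - 70)
  expect_gt(spec$df, 0)
  expect_error(cfa_spec(list(f1 = c("a", "b"), f2 = c("b", "c"))),
               "two factors|identified")
})

test_that("a zero-residual correlation matrix is recovered exactly", {
  spec <- cfa_spec()
  set.seed(81)
  lam <- runif(34, 0.4, 0.9)
  Phi <- cqival:::.cqi_reference_correlations()
  dimnames(Phi) <- NULL
  R <- make_implied_R(lam, spec, Phi)
  fit <- fit_cfa(R, NULL, spec, N = 500)
  expect_lt(fit$fmin, 1e-8)
  expect_lt(max(abs(fit$loadings - lam)), 1e-4)
  expect_lt(max(abs(fit$phi - Phi)), 1e-4)
  expect_true(fit$converged)
  # weighted fit finds the same zero-residual solution
  W <- matrix(runif(34 * 34, 1, 10), 34, 34); W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(R)
  fitw <- fit_cfa(R, W, spec, N = 500)
  expect_lt(fitw$fmin, 1e-8)
})

test_that("the baseline statistic has its closed form", {
  spec <- cfa_spec()
  set.seed(82)
  lam <- runif(34, 0.5, 0.8)
  R <- make_implied_R(lam, spec, cqival:::.cqi_reference_correlations())
  W <- matrix(runif(34 * 34, 1, 5), 34, 34); W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(R)
  fit <- fit_cfa(R, W, spec, N = 101)
  off <- upper.tri(R)
  expect_equal(fit$chisq_baseline, 100 * sum(W[off] * R[off]^2),
               tolerance = 1e-10)
  expect_equal(fit$df_baseline, 34 * 33 / 2)
})

test_that("discrepancy and indices are invariant to reordering and relabeling", {
  spec <- cfa_spec()
  set.seed(83)
  lam <- runif(34, 0.5, 0.85)
  R <- make_implied_R(lam, spec, cqival:::.cqi_reference_correlations())
  R <- R + 0.02 * (function(p) {E <- matrix(rnorm(p * p), p, p)
    E <- (E + t(E)) / 2; diag(E) <- 0; E})(34)  # perturb off-diagonals
  fit <- fit_cfa(R, NULL, spec, N = 300)
  # permute items
  perm <- sample(34)
  Rp <- R[perm, perm]
  fit_p <- fit_cfa(Rp, NULL, spec, N = 300)
  expect_equal(fit_p$fmin, fit$fmin, tolerance = 1e-6)
  # permute factor labels (reorder subscales in the map)
  map <- cqi_item_map()
  spec2 <- cfa_spec(rev(lapply(map$subscales, `[[`, "items")))
  fit_f <- fit_cfa(R, NULL, spec2, N = 300)
  expect_equal(fit_f$fmin, fit$fmin, tolerance = 1e-6)
})

test_that("a coarse grid search confirms the optimizer on a small model", {
  # two factors, two items each, symmetric truth so the optimum lies on
  # the (a, b, phi) slice searchable by brute force
  spec <- cfa_spec(list(f1 = c("i1", "i2"), f2 = c("i3", "i4")))
  a0 <- 0.7; b0 <- 0.6; phi0 <- 0.4
  R <- matrix(c(1, a0 * a0, a0 * b0 * phi0, a0 * b0 * phi0,
                a0 * a0, 1, a0 * b0 * phi0, a0 * b0 * phi0,
                a0 * b0 * phi0, a0 * b0 * phi0, 1, b0 * b0,
                a0 * b0 * phi0, a0 * b0 * phi0, b0 * b0, 1), 4, 4)
  # perturb (1,3) and (2,4) jointly: this violates the tetrad constraint
  # r13*r24 = r14*r23, forcing a nonzero minimum, while keeping the
  # problem invariant under the joint swap (1<->2, 3<->4), so the optimum
  # lies on the searched symmetric slice
  R[1, 3] <- R[3, 1] <- R[1, 3] + 0.05
  R[2, 4] <- R[4, 2] <- R[2, 4] + 0.05
  dimnames(R) <- list(spec$items, spec$items)
  fit <- fit_cfa(R, NULL, spec, N = 200)
  expect_gt(fit$fmin, 1e-5)
  grid <- expand.grid(a = seq(0.3, 0.95, 0.005),
                      b = seq(0.3, 0.95, 0.005),
                      phi = seq(0.1, 0.8, 0.005))
  Fgrid <- with(grid, {
    cross <- a * b * phi
    (R[1, 2] - a * a)^2 + (R[3, 4] - b * b)^2 +
      (R[1, 3] - cross)^2 + (R[1, 4] - cross)^2 +
      (R[2, 3] - cross)^2 + (R[2, 4] - cross)^2
  })
  expect_lt(abs(fit$fmin - min(Fgrid)), 1e-3)
})

test_that("fit indices follow their formulas and the two-of-three rule", {
  fi <- fit_indices(100, 50, 1000, 60, 1001)
  expect_equal(fi$cfi, 1 - 50 / 940)
  expect_equal(fi$tli, (1000 / 60 - 100 / 50) / (1000 / 60 - 1))
  expect_equal(fi$rmsea, sqrt(50 / (50 * 1000)))
  expect_equal(fi$verdict, "poor")  # 0.947 / 0.936 fail, rmsea passes

  perfect <- fit_indices(50, 50, 800, 60, 500)
  expect_equal(perfect$cfi, 1)
  expect_equal(perfect$rmsea, 0)

  expect_warning(fi2 <- fit_indices(100, 50, 55, 60, 500), "TLI undefined")
  expect_true(is.na(fi2$tli))

  expect_equal(evaluate_fit(0.96, 0.95, 0.04), "good")
  expect_equal(evaluate_fit(0.83, 0.81, 0.06), "poor")
  expect_equal(evaluate_fit(0.95, 0.94, 0.06), "acceptable")
  expect_equal(evaluate_fit(0.94, 0.94, 0.07), "poor")
  expect_equal(evaluate_fit(NA, 0.96, 0.04), "acceptable")
})

test_that("group-wise CFA reduces to the plain fit and pools identically", {
  sim <- small_sim(n_hospitals = 2, departments_per_hospital = 3,
                   respondents_per_department = 60, seed = 84)
  spec <- cfa_spec(sim$dataset$item_map)
  whole <- cfa_by_group(sim$dataset, group_field = NULL, spec = spec,
                        min_n = 100)
  expect_named(whole, "all")
  d <- sim$dataset$data
  d$grp <- rep(c("g1", "g2"), length.out = nrow(d))
  # duplicate the sample so both groups are identical
  d2 <- rbind(transform(d, grp = "g1"), transform(d, grp = "g2"))
  ds2 <- survey_dataset(d2, sim$dataset$item_map)
  fits <- cfa_by_group(ds2, group_field = "grp", spec = spec, min_n = 100)
  expect_equal(fits$g1$cfi, fits$g2$cfi)
  expect_equal(fits$g1$rmsea, fits$g2$rmsea)
  # a group below the size floor is skipped with a warning
  d$tiny <- c("small", rep("big", nrow(d) - 1))
  expect_warning(
    res <- cfa_by_group(survey_dataset(d, sim$dataset$item_map),
                        group_field = "tiny", spec = spec, min_n = 100),
    "skipped")
  expect_named(res, "big")
})

test_that("department-level CFA treats aggregates as continuous", {
  spec <- cfa_spec(list(f1 = c("i1", "i2", "i3"), f2 = c("i4", "i5", "i6"),
                        f3 = c("i7", "i8", "i9")))
  # departments whose item means follow the factor model exactly
  set.seed(85)
  lam <- rep(0.7, 9)
  Phi <- matrix(0.3, 3, 3); diag(Phi) <- 1
  R <- make_implied_R(lam, spec, Phi)
  X <- exact_cov_data(40, R, seed = 86)   # 40 "departments"
  d <- data.frame(respondent_id = 1:40, hospital_id = "H1",
                  department_id = paste0("D", 1:40))
  for (j in 1:9) d[[paste0("i", j)]] <- X[, j]
  ds <- survey_dataset(d, cqi_item_map())   # map unused by explicit spec
  fi <- department_level_cfa(ds, spec = spec)
  expect_equal(fi$cfi, 1)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$N, 40)
  # a single department cannot be analysed
  d1 <- d[1, ]
  expect_error(department_level_cfa(survey_dataset(d1, cqi_item_map()),
                                    spec = spec), "at least 3")
})
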