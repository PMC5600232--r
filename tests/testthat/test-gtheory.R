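test_that("two-level Henderson estimates match the hand-worked design", {
  vc <- vc_nested_2level(c(1, 2, 3, 3, 4), c("A", "A", "A", "B", "B"))
  expect_equal(vc$ms_within, 5 / 6)
  expect_equal(vc$ms_between, 2.7)
  expect_equal(vc$c_coef, 2.4)
  expect_equal(vc$sigma2_dept, (2.7 - 5 / 6) / 2.4)  # 7/9
  expect_equal(vc$sigma2_res, 5 / 6)
  expect_false(vc$truncated)
  # constant data: both components zero
  vc0 <- vc_nested_2level(rep(3, 6), rep(c("A", "B", "C"), each = 2))
  expect_equal(vc0$sigma2_dept, 0)
  expect_equal(vc0$sigma2_res, 0)
  # label permutation invariance
  set.seed(90)
  y <- rnorm(60); g <- sample(letters[1:6], 60, replace = TRUE)
  relab <- setNames(sample(LETTERS[1:6]), letters[1:6])
  vc1 <- vc_nested_2level(y, g)
  vc2 <- vc_nested_2level(y, relab[g])
  expect_equal(vc1$sigma2_dept, vc2$sigma2_dept)
  expect_equal(vc1$sigma2_res, vc2$sigma2_res)
  # degenerate designs
  expect_error(vc_nested_2level(1:5, rep("A", 5)), "2 departments")
  expect_error(vc_nested_2level(1:3, c("A", "B", "C")), "singleton")
})

test_that("unbalanced estimators reduce to classical nested ANOVA when balanced", {
  set.seed(91)
  # 2-level: balanced one-way
  a <- 8; n <- 6
  g <- rep(letters[1:a], each = n)
  y <- rep(rnorm(a, sd = 1), each = n) + rnorm(a * n, sd = 2)
  vc <- vc_nested_2level(y, g)
  fit <- anova(lm(y ~ g))
  msb <- fit$`Mean Sq`[1]; msw <- fit$`Mean Sq`[2]
  expect_equal(vc$c_coef, n)
  expect_equal(vc$sigma2_res, msw)
  expect_equal(vc$sigma2_dept, max(0, (msb - msw) / n))

  # 3-level: balanced a=2 hospitals x b=2 departments x n=2
  h <- rep(c("h1", "h2"), each = 4)
  d <- rep(c("d1", "d2", "d3", "d4"), each = 2)
  y3 <- c(1, 2, 4, 6, 3, 3, 7, 10)
  vc3 <- vc_nested_3level(y3, d, h)
  expect_equal(unname(vc3$k), c(2, 2, 4))   # n, n, b*n
  # direct textbook solution from the mean squares
  mh <- tapply(y3, h, mean); md <- tapply(y3, d, mean)
  ms_res <- sum((y3 - md[d])^2) / (8 - 4)
  ms_d <- sum(2 * (md - mh[rep(c("h1", "h2"), each = 2)])^2) / (4 - 2)
  ms_h <- sum(4 * (mh - mean(y3))^2) / 1
  expect_equal(unname(vc3$ms), c(ms_res, ms_d, ms_h))
  expect_equal(vc3$sigma2_res, ms_res)
  expect_equal(vc3$sigma2_dept, max(0, (ms_d - ms_res) / 2))
  expect_equal(vc3$sigma2_hosp,
               max(0, (ms_h - ms_res - 2 * (ms_d - ms_res) / 2) / 4))
})

test_that("estimators are unbiased before truncation", {
  set.seed(92)
  s2_d <- 0.5; s2_res <- 2
  reps <- 1000
  est <- replicate(reps, {
    sizes <- sample(3:8, 10, replace = TRUE)
    g <- rep(seq_along(sizes), sizes)
    y <- rep(rnorm(10, sd = sqrt(s2_d)), sizes) +
      rnorm(sum(sizes), sd = sqrt(s2_res))
    vc <- vc_nested_2level(y, g)
    # undo truncation to test the raw estimator
    c((vc$ms_between - vc$ms_within) / vc$c_coef, vc$sigma2_res)
  })
  se_d <- sd(est[1, ]) / sqrt(reps)
  se_r <- sd(est[2, ]) / sqrt(reps)
  expect_lt(abs(mean(est[1, ]) - s2_d), 2 * se_d)
  expect_lt(abs(mean(est[2, ]) - s2_res), 2 * se_r)
})

test_that("a null hospital stratum is frequently truncated to zero", {
  set.seed(93)
  reps <- 200
  out <- replicate(reps, {
    sizes <- sample(4:8, 18, replace = TRUE)   # 18 departments
    hosp <- rep(rep(1:6, each = 3), sizes)
    dept <- rep(1:18, sizes)
    y <- rep(rnorm(18, sd = 0.3), sizes) + rnorm(sum(sizes))
    vc <- vc_nested_3level(y, dept, hosp)
    c(vc$sigma2_hosp, vc$truncated[["hosp"]])
  })
  expect_gte(mean(out[2, ]), 0.40)
  expect_lt(abs(median(out[1, ])), 0.02)
})

test_that("three-level components are recovered from a known hierarchy", {
  # own-contribution regime: residual 0.404, department 0.014, hospital
  # 0.020; 500 departments in 25 hospitals; mean of 10 replicates
  set.seed(94)
  truth <- c(res = 0.404, dept = 0.014, hosp = 0.020)
  est <- replicate(10, {
    n_h <- 25; d_per_h <- 20
    sizes <- sample(30, n_h * d_per_h, replace = TRUE) + 15
    hosp <- rep(rep(1:n_h, each = d_per_h), sizes)
    dept <- rep(seq_len(n_h * d_per_h), sizes)
    y <- rep(rnorm(n_h, sd = sqrt(truth["hosp"])), tapply(sizes,
             rep(1:n_h, each = d_per_h), sum)) +
      rep(rnorm(n_h * d_per_h, sd = sqrt(truth["dept"])), sizes) +
      rnorm(sum(sizes), sd = sqrt(truth["res"]))
    vc <- vc_nested_3level(y, dept, hosp)
    c(vc$sigma2_res, vc$sigma2_dept, vc$sigma2_hosp)
  })
  m <- rowMeans(est)
  expect_lt(abs(m[1] - truth["res"]) / truth["res"], 0.20)
  expect_lt(abs(m[2] - truth["dept"]) / truth["dept"], 0.20)
  expect_lt(abs(m[3] - truth["hosp"]) / truth["hosp"], 0.20)
})

test_that("pooling averages components and recomputes shares", {
  v1 <- vc_nested_2level(c(1, 2, 3, 3, 4), c("A", "A", "A", "B", "B"))
  expect_equal(pool_components(list(v1, v1))$sigma2_dept, v1$sigma2_dept)
  mk <- function(res, dept, hosp) {
    structure(list(sigma2_res = res, sigma2_dept = dept,
                   sigma2_hosp = hosp, design = "p:d:h",
                   truncated = FALSE), class = "cqi_vc")
  }
  p <- pool_components(list(mk(0.058, 0.002, 0), mk(0.060, 0.004, 0)))
  expect_equal(p$sigma2_res, 0.059)
  expect_equal(p$sigma2_dept, 0.003)
  expect_equal(p$shares$share_dept_pct, 5)   # 0.003/0.062 = 4.84 -> 5
  expect_equal(p$shares$share_hosp_pct, 0)
  expect_equal(p$shares$ratio_hosp, 0)
  expect_error(pool_components(list(v1, mk(1, 1, 1))), "mixed designs")
})

test_that("SEM and G formulas behave across their stated limits", {
  adm <- list(sigma2_res = 0.059, sigma2_dept = 0.003, sigma2_hosp = 0)
  expect_equal(sem_department(adm, 100), sqrt(0.00059))
  expect_lt(sem_department(adm, 100), 0.025)
  expect_equal(sem_department(adm, 400), sem_department(adm, 100) / 2)
  expect_equal(sem_hospital(adm, 10, 100), sqrt(0.003 / 10 + 0.059 / 1000))
  # sigma2_dept = 0 collapses the hospital SEM to a department SEM with
  # n_d * n_p respondents
  nodept <- list(sigma2_res = 0.2, sigma2_dept = 0, sigma2_hosp = 0.01)
  expect_equal(sem_hospital(nodept, 5, 40), sem_department(nodept, 200))
  # G coefficient limits
  expect_equal(g_coefficient(list(sigma2_res = 1, sigma2_dept = 0), 10), 0)
  expect_equal(g_coefficient(list(sigma2_res = 1, sigma2_dept = 1), 1), 0.5)
  doc <- list(sigma2_res = 0.49, sigma2_dept = 0.006)
  expect_equal(g_coefficient(doc, 50), 0.006 / (0.006 + 0.49 / 50))
  # G and SEM are consistent: G = obj / (obj + SEM^2)
  expect_equal(g_coefficient(adm, 80),
               0.003 / (0.003 + sem_department(adm, 80)^2))
  expect_equal(g_coefficient(adm, 80, 7),
               adm$sigma2_hosp /
                 (adm$sigma2_hosp + sem_hospital(adm, 7, 80)^2))
})

test_that("minimum-sample solvers respect grid and threshold conventions", {
  expect_equal(min_respondents(list(sigma2_res = 0.360), 0.10), 50)
  expect_equal(min_respondents(list(sigma2_res = 0.805), 0.10), 100)
  expect_equal(min_departments(list(sigma2_res = 0.1, sigma2_dept = 0.5),
                               100, Inf), 1)
  # with a negligible residual term, halving sigma2_dept halves n_d
  big <- list(sigma2_res = 1e-6, sigma2_dept = 0.04)
  half <- list(sigma2_res = 1e-6, sigma2_dept = 0.02)
  expect_equal(min_departments(half, 1000, 0.05),
               ceiling(min_departments(big, 1000, 0.05) / 2))
  expect_error(min_respondents(list(sigma2_res = 0), 0.1), "positive")
})

test_that("the D-study surface reproduces the scalar operations", {
  comp <- cqi_reference_components()
  dst <- dstudy_grid(comp)
  srf <- dst$surface
  row <- srf[srf$subscale == "communication_doctors" &
               srf$level == "department" & srf$n_p == 50, ]
  doc <- comp[comp$subscale == "communication_doctors", ]
  expect_equal(row$sem, sem_department(doc, 50))
  expect_equal(row$g, g_coefficient(doc, 50))
  expect_equal(row$g, 0.006 / (0.006 + 0.49 / 50))
  hrow <- srf[srf$subscale == "own_contribution" & srf$level == "hospital" &
                srf$n_p == 100 & srf$n_d == 8, ]
  own <- comp[comp$subscale == "own_contribution", ]
  expect_equal(hrow$sem, sem_hospital(own, 8, 100))
  # SEM decreases and G increases along the respondent grid
  dep <- srf[srf$subscale == "admission" & srf$level == "department", ]
  expect_true(all(diff(dep$sem[order(dep$n_p)]) < 0))
  expect_true(all(diff(dep$g[order(dep$n_p)]) >= 0))
  # every four-point subscale except communication-about-medication is
  # satisfied with 50 respondents under SEM < 0.10
  m4 <- dst$minima[dst$minima$kind == "four_point", ]
  expect_equal(m4$min_respondents[m4$subscale != "communication_medication"],
               rep(50, 6))
  expect_equal(
    m4$min_respondents[m4$subscale == "communication_medication"], 100)
  # a one-point grid reduces to the scalar operations
  one <- dstudy_grid(comp[1, ], n_p_grid = 100, n_d_grid = 10)
  expect_equal(one$surface$sem[one$surface$level == "department"],
               sem_department(comp[1, ], 100))
})

test_that("REML agrees with the Henderson path on balanced designs", {
  # on a balanced one-way layout with a positive between component, the
  # REML and analogous-ANOVA estimators coincide
  set.seed(95)
  g <- rep(1:12, each = 7)
  y <- rep(rnorm(12, sd = 1), each = 7) + rnorm(84, sd = 1.5)
  vc <- vc_nested_2level(y, g)
  fit <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE)
  vcm <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(vc$sigma2_dept, vcm$vcov[vcm$grp == "g"], tolerance = 1e-6)
  expect_equal(vc$sigma2_res, vcm$vcov[vcm$grp == "Residual"],
               tolerance = 1e-6)
  # on an unbalanced design the two stay close without being identical
  set.seed(96)
  sizes <- sample(4:12, 15, replace = TRUE)
  gu <- rep(1:15, sizes)
  yu <- rep(rnorm(15, sd = 1), sizes) + rnorm(sum(sizes), sd = 1.5)
  vcu <- vc_nested_2level(yu, gu)
  fitu <- lme4::lmer(yu ~ 1 + (1 | gu), REML = TRUE)
  vcmu <- as.data.frame(lme4::VarCorr(fitu))
  expect_equal(vcu$sigma2_dept, vcmu$vcov[vcmu$grp == "gu"],
               tolerance = 0.35)
  expect_equal(vcu$sigma2_res, vcmu$vcov[vcmu$grp == "Residual"],
               tolerance = 0.1)
})
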