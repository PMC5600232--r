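test_that("generation is deterministic for a fixed seed", {
  cfg <- sim_config(n_hospitals = 2, departments_per_hospital = 3,
                    respondents_per_department = c(10, 30), seed = 99)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(s1$dataset$data, s2$dataset$data)
  expect_identical(s1$truth$latent_scores, s2$truth$latent_scores)
  s3 <- simulate_survey(sim_config(n_hospitals = 2,
                                   departments_per_hospital = 3,
                                   respondents_per_department = c(10, 30),
                                   seed = 100))
  expect_false(identical(s1$dataset$data, s3$dataset$data))
})

test_that("invalid configurations are rejected", {
  badR <- diag(9); badR[1, 2] <- badR[2, 1] <- 1.5
  expect_error(sim_config(R = badR), "positive semi-definite")
  comp <- cqi_reference_components()
  comp$sigma2_res[1] <- -1
  expect_error(sim_config(components = comp), "non-negative")
  expect_error(sim_config(lambda = 1.2), "lambda")
})

test_that("zero group-level variance yields near-zero intraclass correlation", {
  comp <- cqi_reference_components()
  comp$sigma2_dept <- 0
  comp$sigma2_hosp <- 0
  sim <- simulate_survey(sim_config(n_hospitals = 10,
                                    departments_per_hospital = 20,
                                    respondents_per_department = 100,
                                    components = comp, seed = 7))
  z <- sim$truth$latent_scores
  dept <- sim$dataset$data$department_id
  for (s in c("admission", "communication_nurses", "feeling_safety")) {
    vc <- vc_nested_2level(z[, s], dept)
    icc <- vc$sigma2_dept / (vc$sigma2_dept + vc$sigma2_res)
    expect_lt(abs(icc), 0.01)
  }
})

test_that("four-point category proportions match the threshold rectangles", {
  sim <- small_sim(n_hospitals = 5, departments_per_hospital = 5,
                   respondents_per_department = 200, seed = 13)
  d <- sim$dataset$data
  tau <- sim$truth$tau$communication_nurses
  expected <- diff(c(0, pnorm(tau), 1))
  for (it in c("Q6", "Q7", "Q8")) {
    obs <- tabulate(d[[it]], 4) / nrow(d)
    expect_lt(max(abs(obs - expected)), 0.02)   # n = 5000 per item
  }
  # binary yes-rate
  expect_lt(abs(mean(d$Q4a) - pnorm(-sim$truth$tau_b[["admission"]])), 0.03)
})

test_that("cross-subscale item association approximates lambda^2 R_jk", {
  # patient-level polychoric between items of different subscales is
  # attenuated by the loading on each side; group-level effects in the
  # default components dilute the residual correlation by < 6%
  cfg <- sim_config(n_hospitals = 2, departments_per_hospital = 5,
                    respondents_per_department = 5000, seed = 17)
  sim <- simulate_survey(cfg)
  d <- sim$dataset$data
  comp <- cfg$components
  atten <- function(j, k) {  # share of total latent sd that is residual
    sqrt(comp$sigma2_res[j] / sum(comp[j, c("sigma2_res", "sigma2_dept",
                                            "sigma2_hosp")])) *
      sqrt(comp$sigma2_res[k] / sum(comp[k, c("sigma2_res", "sigma2_dept",
                                              "sigma2_hosp")]))
  }
  # nurses (j=2) vs doctors (j=3): R = 0.56
  rho <- estimate_polychoric(d$Q6, d$Q9)$rho
  expect_lt(abs(rho - 0.8^2 * 0.56 * atten(2, 3)), 0.03)
  # safety (j=8) vs pain (j=6): R = 0.41
  rho2 <- estimate_polychoric(d$Q27, d$Q21)$rho
  expect_lt(abs(rho2 - 0.8^2 * 0.41 * atten(8, 6)), 0.03)
})

test_that("latent variance decomposes into the configured components", {
  sim <- simulate_survey(sim_config(n_hospitals = 15,
                                    departments_per_hospital = 15,
                                    respondents_per_department = 40,
                                    seed = 23))
  z <- sim$truth$latent_scores[, "own_contribution"]
  truth <- cqi_reference_components()
  truth <- truth[truth$subscale == "own_contribution", ]
  total <- truth$sigma2_res + truth$sigma2_dept + truth$sigma2_hosp
  expect_lt(abs(var(z) - total) / total, 0.10)
})

test_that("missingness injection hits its target rate and mechanism", {
  sim <- small_sim(n_hospitals = 4, departments_per_hospital = 5,
                   respondents_per_department = 50, seed = 29)
  expect_identical(inject_missingness(sim$dataset, "MCAR", 0,
                                      seed = 1)$data,
                   sim$dataset$data)
  # MCAR: binomial 3-SE band around 0.10 (n cells = 1000 * 34 = 34000;
  # band below is the spec'd 1e5-cell band, conservative here)
  dm <- inject_missingness(sim$dataset, "MCAR", 0.10, seed = 2)
  items <- map_items(sim$dataset$item_map)
  frac <- mean(is.na(as.matrix(dm$data[items])))
  n_cells <- nrow(dm$data) * length(items)
  se3 <- 3 * sqrt(0.1 * 0.9 / n_cells)
  expect_lt(abs(frac - 0.10), se3)
  # MAR doubling on one category roughly doubles that category's rate
  w <- setNames(rep(1, 2), c("male", "female")); w["female"] <- 2
  dmar <- inject_missingness(sim$dataset, "MAR", 0.10, seed = 3,
                             covariate = "sex", weights = w)
  by_cat <- vapply(split(as.data.frame(is.na(as.matrix(dmar$data[items]))),
                         dmar$data$sex),
                   function(b) mean(as.matrix(b)), numeric(1))
  expect_gt(by_cat[["female"]] / by_cat[["male"]], 1.6)
  expect_lt(by_cat[["female"]] / by_cat[["male"]], 2.4)
  expect_error(inject_missingness(sim$dataset, "MCAR", 1.2), "rate")
})
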