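#' Configuration for the end-to-end validation pipeline
#'
#' Collects every knob of the pipeline in one object: either a generator
#' configuration ([sim_config()]) or a path to an input CSV, the
#' missingness injected before imputation (simulated inputs only), the
#' number of imputations, the analysis thresholds, and stage toggles.
#'
#' @param generator A [sim_config()], or `NULL` when `input_csv` is given.
#' @param input_csv Path to a respondent-level CSV (alternative to
#'   `generator`).
#' @param missing_rate Item missingness injected into simulated data
#'   before imputation.
#' @param m Number of imputations.
#' @param n_iterations Chained-equation cycles.
#' @param seed Root seed for missingness/imputation streams.
#' @param fit_cutoffs Named CFA cutoffs (`cfi`, `tli`, `rmsea`).
#' @param alpha_cutoff Cronbach's alpha acceptance threshold.
#' @param overlap_cutoff Inter-scale overlap threshold.
#' @param sem_thresholds Named SEM thresholds per scale kind.
#' @param cfa_group_field Grouping column for subgroup CFA (`NULL` to
#'   skip subgroup runs).
#' @param cfa_min_n Minimum subgroup size for CFA.
#' @param stages Character vector of stages to run, a subset of
#'   `c("reliability", "cfa", "gtheory", "validity")`.
#' @param out_dir Optional directory for `report.json` / `report.txt`.
#' @return List of class `cqi_pipeline_config`.
#' @export
pipeline_config <- function(generator = sim_config(),
                            input_csv = NULL,
                            missing_rate = 0.05,
                            m = 10, n_iterations = 20, seed = 1L,
                            fit_cutoffs = c(cfi = 0.95, tli = 0.95,
                                            rmsea = 0.06),
                            alpha_cutoff = 0.70, overlap_cutoff = 0.70,
                            sem_thresholds = c(four_point = 0.10,
                                               binary = 0.025),
                            cfa_group_field = "specialty",
                            cfa_min_n = 200L,
                            stages = c("reliability", "cfa", "gtheory",
                                       "validity"),
                            out_dir = NULL) {
  stopifnot(all(sem_thresholds > 0), alpha_cutoff > 0, overlap_cutoff > 0)
  if (is.null(generator) && is.null(input_csv))
    stop("either a generator config or an input CSV is required",
         call. = FALSE)
  structure(list(generator = generator, input_csv = input_csv,
                 missing_rate = missing_rate, m = m,
                 n_iterations = n_iterations, seed = as.integer(seed),
                 fit_cutoffs = fit_cutoffs, alpha_cutoff = alpha_cutoff,
                 overlap_cutoff = overlap_cutoff,
                 sem_thresholds = sem_thresholds,
                 cfa_group_field = cfa_group_field, cfa_min_n = cfa_min_n,
                 stages = stages, out_dir = out_dir),
            class = "cqi_pipeline_config")
}

#' Run the full two-level validation pipeline
#'
#' Orchestrates simulate (or load) -> exclusion filtering -> multiple
#' imputation -> subscale scoring and reliability -> ordinal CFA
#' (individual level, by subgroup, and on department aggregates) ->
#' nested variance components with D-study minima -> construct-validity
#' regression, and assembles a machine-readable report.  Deterministic
#' for fixed seeds.  Warnings raised by any stage (truncations, PSD
#' repairs, skipped subgroups, convergence) are collected into the
#' report's provenance log.  A stage failure halts the run with the stage
#' name; previously completed sections are preserved in the error's
#' `partial` attribute.
#'
#' @param config A [pipeline_config()].
#' @return List of class `cqi_report` with sections `exclusions`, `fit`
#'   (per-group and department-level indices with verdicts),
#'   `reliability`, `components` (per-subscale pooled variance components
#'   with shares), `dstudy` (minimum-sample table), `validity` (two
#'   regression tables), and `provenance`.  Written to
#'   `out_dir/report.json` and `report.txt` when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "cqi_pipeline_config"))
  log <- character(0)
  note <- function(stage, msg) log <<- c(log, paste0("[", stage, "] ", msg))
  report <- list()
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        err <- simpleError(paste0("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e)))
        attr(err, "partial") <- report
        stop(err)
      }),
      warning = function(w) {
        note(stage, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  # -- data ------------------------------------------------------------
  ds <- run_stage("data", {
    if (!is.null(config$input_csv)) load_survey(config$input_csv)
    else {
      sim <- simulate_survey(config$generator)
      report$truth_seed <- config$generator$seed
      inject_missingness(sim$dataset, "MCAR", config$missing_rate,
                         seed = config$seed + 1L)
    }
  })
  excl <- run_stage("exclusions", apply_exclusions(ds))
  report$exclusions <- excl$report
  ds <- excl$dataset
  if (is.null(ds)) stop("no records retained after exclusions", call. = FALSE)

  imp <- run_stage("imputation",
                   impute_survey(ds, m = config$m,
                                 n_iterations = config$n_iterations,
                                 seed = config$seed + 2L))
  report$imputation <- list(m = config$m, rhat = imp$rhat)

  map <- ds$item_map
  subs <- names(map$subscales)

  if ("reliability" %in% config$stages) {
    rel <- run_stage("reliability",
                     reliability_report(imp, config$alpha_cutoff,
                                        config$overlap_cutoff))
    report$reliability <- list(alpha = rel$alpha,
                               overlap_individual = rel$overlap$individual,
                               overlap_department = rel$overlap$department)
  }

  if ("cfa" %in% config$stages) {
    report$fit <- run_stage("cfa", {
      spec <- cfa_spec(map)
      fits <- cfa_by_group(imp, group_field = NULL, spec = spec,
                           min_n = config$cfa_min_n)
      names(fits) <- "all_individual"
      if (!is.null(config$cfa_group_field)) {
        by_g <- cfa_by_group(imp, group_field = config$cfa_group_field,
                             spec = spec, min_n = config$cfa_min_n)
        names(by_g) <- paste0(names(by_g), "_individual")
        fits <- c(fits, by_g)
      }
      fits$department <- department_level_cfa(imp, spec)
      do.call(rbind, lapply(names(fits), function(g) {
        fi <- fits[[g]]
        data.frame(group = g, cfi = fi$cfi, tli = fi$tli, rmsea = fi$rmsea,
                   chisq = fi$chisq_m, df = fi$df_m, n = fi$N,
                   verdict = fi$verdict)
      }))
    })
  }

  if ("gtheory" %in% config$stages) {
    gth <- run_stage("gtheory", {
      per_sub <- lapply(subs, function(s) {
        vc2 <- pool_components(lapply(imp$datasets, function(d) {
          sc <- score_subscales(d)
          vc_nested_2level(sc[[s]], sc$department_id)
        }))
        vc3 <- pool_components(lapply(imp$datasets, function(d) {
          sc <- score_subscales(d)
          vc_nested_3level(sc[[s]], sc$department_id, sc$hospital_id)
        }))
        data.frame(subscale = s, kind = map$subscales[[s]]$kind,
                   sigma2_res = vc3$sigma2_res,
                   sigma2_dept = vc3$sigma2_dept,
                   sigma2_hosp = vc3$sigma2_hosp,
                   share_dept_pct = vc3$shares$share_dept_pct,
                   share_hosp_pct = vc3$shares$share_hosp_pct,
                   ratio_hosp = vc3$shares$ratio_hosp,
                   sigma2_dept_pd = vc2$sigma2_dept,
                   sigma2_res_pd = vc2$sigma2_res)
      })
      comp <- do.call(rbind, per_sub)
      dst <- dstudy_grid(comp, thresholds = config$sem_thresholds)
      list(components = comp, dstudy = dst)
    })
    report$components <- gth$components
    report$dstudy <- gth$dstudy$minima
  }

  if ("validity" %in% config$stages) {
    report$validity <- run_stage("validity", list(
      department = as.data.frame(fit_global_rating_model(imp, "dept_rating")),
      hospital = as.data.frame(fit_global_rating_model(imp, "hosp_rating"))))
  }

  report$provenance <- list(seed = config$seed, log = log,
                            n_respondents = nrow(ds$data))
  class(report) <- "cqi_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    txt <- utils::capture.output(print(report))
    writeLines(txt, file.path(config$out_dir, "report.txt"))
  }
  report
}

#' @export
print.cqi_report <- function(x, ...) {
  cat("== CQI validation report ==\n\n-- exclusions --\n")
  print(unlist(x$exclusions))
  if (!is.null(x$fit)) {
    cat("\n-- model fit (CFI / TLI / RMSEA) --\n")
    y <- x$fit
    y[c("cfi", "tli", "rmsea")] <- lapply(y[c("cfi", "tli", "rmsea")],
                                          round, 3)
    print(y[c("group", "cfi", "tli", "rmsea", "n", "verdict")],
          row.names = FALSE)
  }
  if (!is.null(x$reliability)) {
    cat("\n-- reliability (Cronbach's alpha) --\n")
    a <- x$reliability$alpha
    a[c("individual", "department")] <-
      lapply(a[c("individual", "department")], round, 2)
    print(a, row.names = FALSE)
    ov <- x$reliability$overlap_department
    if (nrow(ov) > 0) {
      cat("overlapping department-level pairs:\n")
      print(ov, row.names = FALSE)
    }
  }
  if (!is.null(x$components)) {
    cat("\n-- variance components (p:d:h) --\n")
    cc <- x$components
    cc[c("sigma2_res", "sigma2_dept", "sigma2_hosp")] <-
      lapply(cc[c("sigma2_res", "sigma2_dept", "sigma2_hosp")], round, 3)
    print(cc[c("subscale", "sigma2_res", "sigma2_dept", "sigma2_hosp",
               "share_dept_pct", "share_hosp_pct", "ratio_hosp")],
          row.names = FALSE)
  }
  if (!is.null(x$dstudy)) {
    cat("\n-- D-study minimum samples --\n")
    print(x$dstudy, row.names = FALSE)
  }
  if (length(x$provenance$log) > 0) {
    cat("\n-- provenance log --\n")
    cat(paste0("  ", x$provenance$log, collapse = "\n"), "\n")
  }
  invisible(x)
}
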