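#' Construct a survey dataset
#'
#' Wraps a respondent-level data frame together with its item map and
#' provenance metadata.  One row per respondent; required columns are
#' `respondent_id`, `hospital_id`, `department_id`, `specialty`, the item
#' columns named in the map, the two global-rating columns, the covariates
#' and the admission-gate item.
#'
#' @param data Data frame, one row per respondent.
#' @param item_map A [cqi_item_map()].
#' @param provenance List of free-form metadata (source file, generator
#'   configuration, seed).
#' @return An object of class `cqi_survey`.
#' @export
survey_dataset <- function(data, item_map = cqi_item_map(),
                           provenance = list()) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("survey dataset is empty", call. = FALSE)
  for (col in c("hospital_id", "department_id"))
    if (!col %in% names(data))
      stop("mandatory column missing: ", col, call. = FALSE)
  if (!"respondent_id" %in% names(data))
    data$respondent_id <- seq_len(nrow(data))
  structure(list(data = data, item_map = item_map, provenance = provenance),
            class = "cqi_survey")
}

#' @export
print.cqi_survey <- function(x, ...) {
  d <- x$data
  cat("<cqi_survey>", nrow(d), "respondents,",
      length(unique(paste(d$hospital_id, d$department_id))), "departments,",
      length(unique(d$hospital_id)), "hospitals\n")
  items <- intersect(map_items(x$item_map), names(d))
  miss <- mean(is.na(as.matrix(d[items])))
  cat(sprintf("  %d mapped item columns, %.1f%% item cells missing\n",
              length(items), 100 * miss))
  invisible(x)
}

#' @export
dim.cqi_survey <- function(x) dim(x$data)

#' Read a respondent-level survey CSV
#'
#' Reads a comma-separated UTF-8 file with a header row into a
#' [survey_dataset()].  Missing values are empty cells or `NA`.  Item codes
#' outside the legal range of their scale (1--4 for four-point items, 0/1
#' for binary items, 0--10 for global ratings) are set to missing; the
#' number of such replacements is reported in a warning and stored in the
#' provenance.
#'
#' @param path Path to the CSV file.
#' @param item_map A [cqi_item_map()] describing the expected columns.
#' @return A `cqi_survey`.
#' @seealso [write_survey()]
#' @export
load_survey <- function(path, item_map = cqi_item_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(d) == 0L) stop("empty survey file: ", path, call. = FALSE)
  for (col in c("hospital_id", "department_id"))
    if (!col %in% names(d))
      stop("mandatory column missing from ", path, ": ", col, call. = FALSE)

  kinds <- map_item_kinds(item_map)
  n_out_of_range <- 0L
  range_ok <- function(v, lo, hi) !is.na(v) & (v < lo | v > hi | v != round(v))
  for (it in intersect(names(kinds), names(d))) {
    v <- suppressWarnings(as.numeric(d[[it]]))
    bad <- if (kinds[[it]] == "four_point") range_ok(v, 1, 4) else range_ok(v, 0, 1)
    n_out_of_range <- n_out_of_range + sum(bad)
    v[bad] <- NA_real_
    d[[it]] <- v
  }
  for (rt in intersect(item_map$global_rating_fields, names(d))) {
    v <- suppressWarnings(as.numeric(d[[rt]]))
    bad <- range_ok(v, 0, 10)
    n_out_of_range <- n_out_of_range + sum(bad)
    v[bad] <- NA_real_
    d[[rt]] <- v
  }
  gate <- item_map$admission_gate_field
  if (gate %in% names(d)) {
    v <- suppressWarnings(as.numeric(d[[gate]]))
    bad <- range_ok(v, 0, 1)
    n_out_of_range <- n_out_of_range + sum(bad)
    v[bad] <- NA_real_
    d[[gate]] <- v
  }
  if (n_out_of_range > 0L)
    warning(n_out_of_range, " out-of-range codes set to missing",
            call. = FALSE)
  survey_dataset(d, item_map,
                 provenance = list(source = path,
                                   n_out_of_range = n_out_of_range))
}

#' Write a survey dataset to CSV
#'
#' Inverse of [load_survey()]: missing values are written as empty cells.
#'
#' @param ds A `cqi_survey`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(ds, path) {
  stopifnot(inherits(ds, "cqi_survey"))
  write.csv(ds$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the standard exclusion filters
#'
#' A questionnaire is excluded when (a) the respondent gave a negative or
#' no answer to the gate question "were you admitted to hospital within the
#' last 12 months", or (b) fewer than half of the core items were
#' completed.  The gate is checked first, so a record failing both rules is
#' counted once under the gate reason; a record with exactly half of the
#' core items completed is retained (the rule is a strict "less than
#' half").
#'
#' @param ds A `cqi_survey`.
#' @return A list with elements `dataset` (the retained `cqi_survey`; may
#'   have zero rows, in which case `dataset` is `NULL`) and `report`, a
#'   list with counts `n_received`, `n_excluded_no_admission`,
#'   `n_excluded_incomplete`, `n_retained`.
#' @examples
#' ds <- simulate_survey(sim_config(n_hospitals = 2,
#'   departments_per_hospital = 2, respondents_per_department = 20,
#'   seed = 1))$dataset
#' apply_exclusions(ds)$report
#' @export
apply_exclusions <- function(ds) {
  stopifnot(inherits(ds, "cqi_survey"))
  d <- ds$data
  map <- ds$item_map
  gate <- map$admission_gate_field
  gate_val <- if (gate %in% names(d)) d[[gate]] else rep(NA_real_, nrow(d))
  gate_fail <- is.na(gate_val) | gate_val != 1

  core <- intersect(map$core_items, names(d))
  if (length(core) == 0L) stop("no core items present in data", call. = FALSE)
  n_done <- rowSums(!is.na(as.matrix(d[core])))
  incomplete <- n_done < length(core) / 2

  excl_gate <- gate_fail
  excl_incomplete <- !gate_fail & incomplete
  keep <- !excl_gate & !excl_incomplete

  report <- list(n_received = nrow(d),
                 n_excluded_no_admission = sum(excl_gate),
                 n_excluded_incomplete = sum(excl_incomplete),
                 n_retained = sum(keep))
  dataset <- if (any(keep)) {
    survey_dataset(d[keep, , drop = FALSE], map,
                   provenance = c(ds$provenance, list(exclusions = report)))
  } else NULL
  list(dataset = dataset, report = report)
}

#' Gross and net response rates
#'
#' @param n_distributed Number of questionnaires distributed (> 0).
#' @param n_returned Number returned.
#' @param n_excluded Number of returned questionnaires excluded.
#' @return List with `gross_rate` and `net_rate` (percent, rounded to one
#'   decimal) and `n_net`.
#' @examples
#' response_rate_summary(74090, 23476, 552)
#' @export
response_rate_summary <- function(n_distributed, n_returned, n_excluded) {
  if (n_distributed <= 0) stop("n_distributed must be positive", call. = FALSE)
  if (n_excluded < 0 || n_returned < n_excluded || n_distributed < n_returned)
    stop("require 0 <= n_excluded <= n_returned <= n_distributed",
         call. = FALSE)
  n_net <- as.integer(n_returned - n_excluded)
  list(gross_rate = round(100 * n_returned / n_distributed, 1),
       net_rate = round(100 * n_net / n_distributed, 1),
       n_net = n_net)
}
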