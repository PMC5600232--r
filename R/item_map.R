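#' Item-to-subscale map for a CQI-style questionnaire
#'
#' An item map describes the measurement structure of the instrument: which
#' items belong to which subscale, whether each subscale is scored on a
#' four-point Likert scale (1 = Never ... 4 = Always) or a binary yes/no
#' scale (1 = yes, 0 = no), plus the names of the two 0--10 global-rating
#' fields, the demographic covariate fields, and the admission-gate item
#' used by the exclusion filter.
#'
#' The default map is the CQI Inpatient Hospital Care structure: nine
#' subscales covering 34 items, with *admission* and *information at
#' discharge* binary and the remaining seven four-point.
#'
#' @param subscales Named list; each element is a list with fields
#'   `items` (character vector of item IDs) and `kind`
#'   (`"four_point"` or `"binary"`).
#' @param global_rating_fields Character vector of length 2, names of the
#'   department and hospital global-rating columns (0--10 integers).
#' @param covariate_fields Character vector of covariate column names.
#' @param admission_gate_field Name of the yes/no item "hospitalized in the
#'   last 12 months" used by the exclusion gate.
#' @param core_items Character vector of item IDs used by the completion
#'   filter; defaults to all subscale items.
#'
#' @return An object of class `cqi_item_map`.
#' @examples
#' map <- cqi_item_map()
#' map$subscales$pain_management$items
#' @export
cqi_item_map <- function(subscales = NULL,
                         global_rating_fields = c(department = "dept_rating",
                                                  hospital = "hosp_rating"),
                         covariate_fields = c("age_band", "sex", "education",
                                              "physical_health", "psych_health",
                                              "origin", "n_admissions"),
                         admission_gate_field = "admitted_12m",
                         core_items = NULL) {
  if (is.null(subscales)) subscales <- .cqi_default_subscales()
  stopifnot(is.list(subscales), length(subscales) > 0L)
  for (nm in names(subscales)) {
    s <- subscales[[nm]]
    if (!is.character(s$items) || length(s$items) < 1L)
      stop("subscale '", nm, "' has no items", call. = FALSE)
    if (!s$kind %in% c("four_point", "binary"))
      stop("subscale '", nm, "' has unknown scale kind '", s$kind, "'",
           call. = FALSE)
  }
  all_items <- unlist(lapply(subscales, `[[`, "items"), use.names = FALSE)
  if (anyDuplicated(all_items))
    stop("an item is assigned to two subscales: ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "),
         call. = FALSE)
  if (is.null(core_items)) core_items <- all_items
  structure(list(subscales = subscales,
                 global_rating_fields = global_rating_fields,
                 covariate_fields = covariate_fields,
                 admission_gate_field = admission_gate_field,
                 core_items = core_items),
            class = "cqi_item_map")
}

# Nine subscales, item counts 10/3/2/5/3/2/2/3/4; admission and discharge
# information are yes/no, all others four-point.
.cqi_default_subscales <- function() {
  list(
    admission = list(
      items = paste0("Q4", letters[1:10]), kind = "binary"),
    communication_nurses = list(
      items = c("Q6", "Q7", "Q8"), kind = "four_point"),
    communication_doctors = list(
      items = c("Q9", "Q10"), kind = "four_point"),
    own_contribution = list(
      items = c("Q13", "Q14", "Q15", "Q17", "Q25"), kind = "four_point"),
    explanation_treatment = list(
      items = c("Q18", "Q19", "Q20"), kind = "four_point"),
    pain_management = list(
      items = c("Q21", "Q22"), kind = "four_point"),
    communication_medication = list(
      items = c("Q23", "Q24"), kind = "four_point"),
    feeling_safety = list(
      items = c("Q27", "Q28", "Q29"), kind = "four_point"),
    information_discharge = list(
      items = c("Q31", "Q32", "Q33", "Q34"), kind = "binary")
  )
}

#' @export
print.cqi_item_map <- function(x, ...) {
  cat("<cqi_item_map>", length(x$subscales), "subscales,",
      length(map_items(x)), "items\n")
  for (nm in names(x$subscales))
    cat(sprintf("  %-26s %-10s %2d items\n", nm, x$subscales[[nm]]$kind,
                length(x$subscales[[nm]]$items)))
  invisible(x)
}

#' All item IDs of an item map, in subscale order
#' @param map A [cqi_item_map()].
#' @return Character vector of item IDs.
#' @export
map_items <- function(map) {
  unlist(lapply(map$subscales, `[[`, "items"), use.names = FALSE)
}

#' Scale kind per item
#' @param map A [cqi_item_map()].
#' @return Named character vector, `"four_point"` or `"binary"` per item ID.
#' @export
map_item_kinds <- function(map) {
  out <- unlist(lapply(map$subscales, function(s)
    setNames(rep(s$kind, length(s$items)), s$items)))
  names(out) <- map_items(map)
  out
}

#' Subscale membership per item
#' @param map A [cqi_item_map()].
#' @return Named character vector mapping item ID to subscale name.
#' @export
map_item_subscales <- function(map) {
  out <- unlist(lapply(names(map$subscales), function(nm)
    setNames(rep(nm, length(map$subscales[[nm]]$items)),
             map$subscales[[nm]]$items)))
  out
}
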