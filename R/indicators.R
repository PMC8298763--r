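# The nine binary claims-based severity indicators: deep brain
# stimulation, fall, hallucinations, walker, wheelchair, specialty bed,
# dementia, skilled nursing facility, hospice. Each is true iff at least
# one medical claim in the study period matches its code set (and its
# required setting, where one applies); one claim may trigger several
# indicators.

#' Extract the nine severity-indicator profiles
#'
#' @param medical_claims medical claims table (any number of patients).
#' @param code_sets named list of the nine [code_set()]s, e.g. from
#'   [read_code_sets()].
#' @param period a [study_period()]; claims outside it are ignored
#'   (indicators are captured at any point during the study year).
#' @param patient_ids patient universe; patients with no matching claims
#'   get all-`FALSE` rows. Default: the patients present in
#'   `medical_claims`.
#' @return data.frame with one row per patient: nine logical columns named
#'   after the indicators, plus `<indicator>_first_date` columns holding
#'   the earliest matching claim date (`NA` when the indicator is false).
#' @export
extract_indicators <- function(medical_claims, code_sets,
                               period = study_period(),
                               patient_ids = NULL) {
  missing_sets <- setdiff(INDICATOR_NAMES, names(code_sets))
  if (length(missing_sets) > 0) {
    stopf("missing code set(s) for indicator(s): %s",
          paste(missing_sets, collapse = ", "))
  }
  med <- data.table::as.data.table(medical_claims)
  med <- med[service_date >= period$start_date &
               service_date <= period$end_date]
  if (is.null(patient_ids)) patient_ids <- unique(med$patient_id)
  patient_ids <- as.character(patient_ids)

  out <- data.frame(patient_id = patient_ids, stringsAsFactors = FALSE)
  for (nm in INDICATOR_NAMES) {
    cs <- code_sets[[nm]]
    hit <- codes_match(cs, med$code_system, med$code, med$setting)
    first <- rep(as.Date(NA), length(patient_ids))
    flag <- rep(FALSE, length(patient_ids))
    if (any(hit)) {
      agg <- med[hit, list(first_date = min(service_date)),
                 by = "patient_id"]
      idx <- match(agg$patient_id, patient_ids)
      ok <- !is.na(idx)
      flag[idx[ok]] <- TRUE
      first[idx[ok]] <- agg$first_date[ok]
    }
    out[[nm]] <- flag
    out[[paste0(nm, "_first_date")]] <- first
  }
  out
}

#' Indicator prevalence by assigned severity group
#'
#' Counts and percentages (rounded half-up to one decimal) of each
#' indicator overall and within the mild-moderate and APD groups, under
#' one classification rule.
#'
#' @param profiles indicator table from [extract_indicators()].
#' @param classifications classification table from [classify_cohort()]
#'   (or any table with `patient_id` and `is_apd`); if several rules are
#'   present, `rule` selects one.
#' @param rule rule name to tabulate under (default: first rule present).
#' @return data.frame with one row per indicator: counts and percentages
#'   for overall / mild-moderate / APD.
#' @export
indicator_prevalence <- function(profiles, classifications, rule = NULL) {
  cls <- as.data.frame(classifications)
  if ("rule" %in% names(cls)) {
    rule <- rule %||% cls$rule[1]
    cls <- cls[cls$rule == rule, , drop = FALSE]
  }
  if (anyDuplicated(cls$patient_id)) {
    stopf("multiple classifications per patient; pass a single rule")
  }
  idx <- match(profiles$patient_id, cls$patient_id)
  if (any(is.na(idx))) {
    stopf("%d profile patient(s) missing a classification", sum(is.na(idx)))
  }
  apd <- cls$is_apd[idx]
  n_all <- length(apd)
  n_apd <- sum(apd)
  n_mild <- n_all - n_apd
  if (n_apd == 0 || n_mild == 0) {
    stopf("a severity group is empty; prevalence percentages undefined")
  }
  rows <- lapply(INDICATOR_NAMES, function(nm) {
    x <- profiles[[nm]]
    data.frame(
      indicator = nm,
      n_overall = sum(x), pct_overall = claims_pct(sum(x), n_all),
      n_mild_moderate = sum(x & !apd),
      pct_mild_moderate = claims_pct(sum(x & !apd), n_mild),
      n_apd = sum(x & apd), pct_apd = claims_pct(sum(x & apd), n_apd),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "group_sizes") <- c(overall = n_all, mild_moderate = n_mild,
                                apd = n_apd)
  out
}
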