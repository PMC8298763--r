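# Cohort construction: the study's sequential inclusion criteria with an
# attrition funnel, and the covariate record used for adjustment
# (age band, sex, race, region, RxHCC risk score, neurologist visit).

AGE_BANDS <- c("65_69", "70_74", "75_79", "GE_80")
COVARIATE_RACES <- c("WHITE", "BLACK", "OTHER")
COVARIATE_REGIONS <- c("NORTHEAST", "MIDWEST", "SOUTH", "WEST")

age_at <- function(birth_date, ref_date) {
  by <- as.POSIXlt(birth_date)
  rd <- as.POSIXlt(ref_date)
  age <- rd$year - by$year
  before_birthday <- rd$mon < by$mon | (rd$mon == by$mon & rd$mday < by$mday)
  age - as.integer(before_birthday)
}

age_band <- function(age) {
  cut(age, breaks = c(65, 70, 75, 80, Inf), labels = AGE_BANDS,
      right = FALSE)
}

#' Apply the study inclusion criteria
#'
#' A patient enters the analytic cohort iff all of the following hold, in
#' this order: (1) at least one inpatient or outpatient claim with a PD
#' diagnosis code during the period; (2) aged 65 or older (at the
#' `age_reference` date); (3) continuously enrolled (all 12 monthly flags);
#' (4) alive throughout the period (no death date, or death after the
#' period end); (5) at least one levodopa dispensing in the period;
#' (6) complete data for all key covariates. Since each criterion is a
#' pure per-patient predicate, the final set does not depend on the filter
#' order — only the funnel counts do.
#'
#' @param beneficiaries table from [read_beneficiaries()].
#' @param medical_claims table from [read_medical_claims()].
#' @param pharmacy_claims table from [read_pharmacy_claims()].
#' @param pd_dx_codeset [code_set()] defining the PD diagnosis (default:
#'   exact normalized ICD-9-CM 332.0, i.e. `"3320"`).
#' @param period a [study_period()].
#' @param ref drug reference table (identifies levodopa-containing drugs
#'   via `counts_as_levodopa`).
#' @param age_reference date at which "aged 65 or older" is evaluated;
#'   default the period start.
#' @return list with `included` (character vector of patient ids) and
#'   `report` (an `inclusion_report` data frame: one row per filter step
#'   with the count surviving it).
#' @export
apply_inclusion_criteria <- function(beneficiaries, medical_claims,
                                     pharmacy_claims,
                                     pd_dx_codeset = pd_diagnosis_code_set(),
                                     period = study_period(),
                                     ref = read_drug_reference(),
                                     age_reference = period$start_date) {
  ben <- data.table::as.data.table(beneficiaries)
  if (nrow(ben) == 0) stopf("beneficiary table is empty: nothing to filter")
  med <- data.table::as.data.table(medical_claims)
  rx <- data.table::as.data.table(pharmacy_claims)

  in_period <- function(d) d >= period$start_date & d <= period$end_date

  dx <- med[in_period(service_date) &
              setting %in% c("INPATIENT", "OUTPATIENT")]
  dx_ids <- unique(dx$patient_id[codes_match(pd_dx_codeset, dx$code_system,
                                             dx$code)])

  levodopa_drugs <- ref$drug_id[ref$counts_as_levodopa]
  ld_ids <- unique(rx$patient_id[rx$drug_id %in% levodopa_drugs &
                                   in_period(rx$fill_date)])

  keep <- ben
  steps <- list(c(criterion = "all beneficiaries"))
  counts <- nrow(keep)
  push <- function(keep, label) {
    steps[[length(steps) + 1L]] <<- c(criterion = label)
    counts <<- c(counts, nrow(keep))
    keep
  }

  keep <- push(keep[patient_id %in% dx_ids],
               "PD diagnosis claim (inpatient/outpatient)")
  keep <- push(keep[age_at(birth_date, age_reference) >= 65L],
               "aged 65 or older")
  keep <- push(keep[!grepl("0", enrollment, fixed = TRUE)],
               "continuously enrolled (A+B+D, all 12 months)")
  keep <- push(keep[is.na(death_date) | death_date > period$end_date],
               "alive throughout the period")
  keep <- push(keep[patient_id %in% ld_ids],
               "at least one levodopa claim")
  keep <- push(keep[sex %in% SEXES & race != "MISSING" &
                      region != "MISSING" & !is.na(rx_risk_score) &
                      !is.na(birth_date)],
               "complete covariate data")

  report <- data.frame(
    step = seq_along(counts) - 1L,
    criterion = vapply(steps, `[[`, "", "criterion"),
    n_remaining = counts,
    stringsAsFactors = FALSE
  )
  class(report) <- c("inclusion_report", "data.frame")
  list(included = keep$patient_id, report = report)
}

#' @export
print.inclusion_report <- function(x, ...) {
  cat("Inclusion funnel:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %d. %-48s %d\n", x$step[i], x$criterion[i],
                x$n_remaining[i]))
  }
  invisible(x)
}

#' Default PD diagnosis code set
#'
#' Exact match on normalized ICD-9-CM 332.0 ("3320"), the standard
#' claims-based PD case definition.
#'
#' @return a [code_set()].
#' @export
pd_diagnosis_code_set <- function() {
  code_set("pd_diagnosis",
           data.frame(system = "DX", code = "3320", match = "EXACT"))
}

#' Build covariate records for included patients
#'
#' Age band at the reference date (65-69 / 70-74 / 75-79 / >=80), sex,
#' race, region, RxHCC risk score (consumed as given) and whether the
#' patient had any outpatient claim matching the neurologist code set
#' during the period.
#'
#' @param beneficiaries beneficiary rows for the included patients.
#' @param medical_claims medical claims table.
#' @param neurologist_codeset [code_set()] identifying neurologist visits
#'   (provider specialty abstracted as a code set).
#' @param period a [study_period()].
#' @param age_reference date at which age bands are computed; default the
#'   period start.
#' @return data.frame with columns `patient_id`, `age_group` (factor,
#'   reference `65_69`), `male`, `race` (reference `WHITE`), `region`
#'   (reference `NORTHEAST`), `rx_risk_score`, `neurologist_visit`.
#' @export
build_covariates <- function(beneficiaries, medical_claims,
                             neurologist_codeset, period = study_period(),
                             age_reference = period$start_date) {
  ben <- data.table::as.data.table(beneficiaries)
  med <- data.table::as.data.table(medical_claims)

  age <- age_at(ben$birth_date, age_reference)
  if (any(is.na(age)) || any(age < 65L)) {
    stopf("covariates requested for %d patient(s) under 65 or with missing %s",
          sum(is.na(age) | age < 65L), "birth date: inclusion not applied?")
  }
  if (any(!ben$race %in% COVARIATE_RACES) ||
      any(!ben$region %in% COVARIATE_REGIONS) ||
      any(is.na(ben$rx_risk_score)) || any(!ben$sex %in% SEXES)) {
    stopf("incomplete covariate value(s): inclusion criteria not applied?")
  }

  visits <- med[service_date >= period$start_date &
                  service_date <= period$end_date &
                  setting == "OUTPATIENT"]
  neuro_ids <- unique(visits$patient_id[
    codes_match(neurologist_codeset, visits$code_system, visits$code)])

  data.frame(
    patient_id = ben$patient_id,
    age_group = factor(age_band(age), levels = AGE_BANDS),
    male = ben$sex == "M",
    race = factor(ben$race, levels = COVARIATE_RACES),
    region = factor(ben$region, levels = COVARIATE_REGIONS),
    rx_risk_score = ben$rx_risk_score,
    neurologist_visit = ben$patient_id %in% neuro_ids,
    stringsAsFactors = FALSE
  )
}
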