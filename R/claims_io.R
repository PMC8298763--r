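# Data model and delimited-text I/O for the claims tables every other
# module consumes. All readers validate row-by-row: invalid rows are
# collected (with their file line numbers) and surfaced, never silently
# dropped.

CODE_SYSTEMS <- c("DX", "PROC", "DME")
SETTINGS <- c("INPATIENT", "OUTPATIENT", "SNF", "HOSPICE", "DME", "OTHER")
SEXES <- c("M", "F")
RACES <- c("WHITE", "BLACK", "OTHER", "MISSING")
REGIONS <- c("NORTHEAST", "MIDWEST", "SOUTH", "WEST", "MISSING")

#' Define a study period
#'
#' An inclusive calendar interval over which daily dosing is reconstructed.
#' Must span at least 30 days so that at least one 30-day window exists.
#'
#' @param start_date,end_date inclusive period bounds (`Date` or ISO-8601
#'   strings). Default: calendar year 2013.
#' @return A `study_period` object with `start_date`, `end_date` and
#'   `n_days`.
#' @examples
#' study_period()                      # calendar year 2013, 365 days
#' study_period("2014-01-01", "2014-12-31")
#' @export
study_period <- function(start_date = "2013-01-01", end_date = "2013-12-31") {
  start_date <- as_date_strict(start_date)
  end_date <- as_date_strict(end_date)
  if (is.na(start_date) || is.na(end_date)) {
    stopf("study period bounds must be valid ISO-8601 dates")
  }
  if (end_date < start_date + 29L) {
    stopf("study period must span at least 30 days (got %d)",
          as.integer(end_date - start_date) + 1L)
  }
  structure(
    list(start_date = start_date, end_date = end_date,
         n_days = as.integer(end_date - start_date) + 1L),
    class = "study_period"
  )
}

#' @export
print.study_period <- function(x, ...) {
  cat(sprintf("<study_period> %s .. %s (%d days)\n",
              format(x$start_date), format(x$end_date), x$n_days))
  invisible(x)
}

#' Normalize a diagnosis/procedure/equipment code
#'
#' Uppercases and strips dots so that ICD-9 dialects written with and
#' without decimal points compare equal ("V43.3" and "v433" both become
#' "V433"). Idempotent.
#'
#' @param code character vector of raw codes.
#' @return normalized character vector.
#' @export
normalize_code <- function(code) {
  gsub(".", "", toupper(trimws(as.character(code))), fixed = TRUE)
}

#' Default column mappings for the claims tables
#'
#' The source files of real claims extracts use proprietary layouts, so the
#' readers take a configurable mapping from canonical field names to file
#' column names. These defaults document the canonical schema (and are the
#' layout the synthetic generator writes).
#'
#' @return named character vector: canonical field -> file column name.
#' @export
pharmacy_schema <- function() {
  c(patient_id = "patient_id", drug_id = "drug_id", fill_date = "fill_date",
    days_supply = "days_supply", quantity = "quantity",
    strength_mg = "strength_mg")
}

#' @rdname pharmacy_schema
#' @export
medical_schema <- function() {
  c(patient_id = "patient_id", service_date = "service_date",
    code_system = "code_system", code = "code", setting = "setting")
}

#' @rdname pharmacy_schema
#' @export
beneficiary_schema <- function() {
  c(patient_id = "patient_id", birth_date = "birth_date", sex = "sex",
    race = "race", region = "region", enrollment = "enrollment",
    death_date = "death_date", rx_risk_score = "rx_risk_score")
}

read_mapped_table <- function(path, dialect, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  dt <- data.table::fread(path, colClasses = "character", sep = "auto",
                          header = TRUE, na.strings = c("", "NA"))
  missing <- setdiff(unname(dialect), names(dt))
  if (length(missing) > 0) {
    stopf("%s file %s is missing required column(s): %s",
          what, path, paste(missing, collapse = ", "))
  }
  dt <- dt[, unname(dialect), with = FALSE]
  data.table::setnames(dt, unname(dialect), names(dialect))
  dt
}

finish_read <- function(dt, bad, reasons, what) {
  rejected <- data.frame(
    line = which(bad) + 1L,  # +1 for the header row
    reason = reasons[bad],
    stringsAsFactors = FALSE
  )
  out <- dt[!bad]
  data.table::setattr(out, "rejected", rejected)
  if (nrow(rejected) > 0) {
    message(sprintf("%s: rejected %d invalid row(s) (lines %s)", what,
                    nrow(rejected),
                    paste(utils::head(rejected$line, 10L), collapse = ", ")))
  }
  out[]
}

#' Rejected rows from a claims reader
#'
#' Every reader validates rows and keeps the failures; this accessor
#' returns them as a data frame of file line numbers and reasons.
#'
#' @param x a table returned by [read_pharmacy_claims()],
#'   [read_medical_claims()] or [read_beneficiaries()].
#' @return data frame with columns `line` and `reason` (zero rows when all
#'   rows validated).
#' @export
rejected_rows <- function(x) {
  attr(x, "rejected") %||%
    data.frame(line = integer(), reason = character())
}

#' Read a pharmacy claims (dispensing event) table
#'
#' One row per dispensing event: patient, drug, fill date, days supply,
#' quantity dispensed and strength (mg of active moiety per unit; for
#' carbidopa/levodopa combinations, mg of the levodopa moiety). Rows
#' violating the field invariants are rejected and reported with their
#' line numbers; retrieve them with [rejected_rows()].
#'
#' @param path delimited text file (comma or tab; auto-detected).
#' @param dialect named character vector mapping canonical field names to
#'   the file's column names; see [pharmacy_schema()].
#' @return data.table of validated claims with typed columns
#'   (`fill_date` as `Date`, `days_supply` integer, `quantity` and
#'   `strength_mg` numeric), carrying a `rejected` attribute.
#' @export
read_pharmacy_claims <- function(path, dialect = pharmacy_schema()) {
  dt <- read_mapped_table(path, dialect, "pharmacy claims")
  n <- nrow(dt)
  fill_date <- as_date_strict(dt$fill_date)
  days_supply <- suppressWarnings(as.numeric(dt$days_supply))
  quantity <- suppressWarnings(as.numeric(dt$quantity))
  strength <- suppressWarnings(as.numeric(dt$strength_mg))

  reasons <- character(n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- why
  }
  flag(is.na(dt$patient_id) | dt$patient_id == "", "missing patient_id")
  flag(is.na(dt$drug_id) | dt$drug_id == "", "missing drug_id")
  flag(is.na(fill_date), "unparseable fill_date")
  flag(is.na(days_supply) | days_supply < 1 |
         days_supply != floor(days_supply),
       "days_supply must be a positive integer")
  flag(is.na(quantity) | quantity <= 0, "quantity must be > 0")
  flag(is.na(strength) | strength <= 0, "strength_mg must be > 0")

  out <- data.table::data.table(
    patient_id = dt$patient_id, drug_id = dt$drug_id, fill_date = fill_date,
    days_supply = as.integer(days_supply), quantity = quantity,
    strength_mg = strength
  )
  finish_read(out, reasons != "", reasons, "pharmacy claims")
}

#' Read a medical claims table
#'
#' One row per claim line: patient, service date, code system (`DX`,
#' `PROC`, `DME`), code and care setting. Codes are normalized with
#' [normalize_code()] on read.
#'
#' @inheritParams read_pharmacy_claims
#' @param dialect see [medical_schema()].
#' @return data.table of validated claims (`service_date` as `Date`),
#'   carrying a `rejected` attribute.
#' @export
read_medical_claims <- function(path, dialect = medical_schema()) {
  dt <- read_mapped_table(path, dialect, "medical claims")
  n <- nrow(dt)
  service_date <- as_date_strict(dt$service_date)
  code_system <- toupper(trimws(ifelse(is.na(dt$code_system), "",
                                       dt$code_system)))
  setting <- toupper(trimws(ifelse(is.na(dt$setting), "", dt$setting)))
  code <- normalize_code(ifelse(is.na(dt$code), "", dt$code))

  reasons <- character(n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- why
  }
  flag(is.na(dt$patient_id) | dt$patient_id == "", "missing patient_id")
  flag(is.na(service_date), "unparseable service_date")
  flag(!code_system %in% CODE_SYSTEMS,
       sprintf("code_system must be one of %s",
               paste(CODE_SYSTEMS, collapse = "/")))
  flag(code == "", "empty code after normalization")
  flag(!setting %in% SETTINGS,
       sprintf("setting must be one of %s", paste(SETTINGS, collapse = "/")))

  out <- data.table::data.table(
    patient_id = dt$patient_id, service_date = service_date,
    code_system = code_system, code = code, setting = setting
  )
  finish_read(out, reasons != "", reasons, "medical claims")
}

#' Read a beneficiary summary table
#'
#' One row per beneficiary: demographics, a 12-character monthly
#' enrollment string (one flag per study month, `1` = enrolled in Parts
#' A+B+D that month), optional death date and the prescription-drug
#' hierarchical condition category (RxHCC) risk score, consumed as a given
#' covariate.
#'
#' @inheritParams read_pharmacy_claims
#' @param dialect see [beneficiary_schema()].
#' @return data.table with typed columns; `enrollment` stays a 12-character
#'   string of 0/1 flags; missing race/region become `"MISSING"`.
#' @export
read_beneficiaries <- function(path, dialect = beneficiary_schema()) {
  dt <- read_mapped_table(path, dialect, "beneficiary summary")
  n <- nrow(dt)
  birth_date <- as_date_strict(dt$birth_date)
  death_date <- as_date_strict(dt$death_date)
  sex <- toupper(trimws(ifelse(is.na(dt$sex), "", dt$sex)))
  race <- toupper(trimws(ifelse(is.na(dt$race), "MISSING", dt$race)))
  region <- toupper(trimws(ifelse(is.na(dt$region), "MISSING", dt$region)))
  enrollment <- gsub("[^01]", "", ifelse(is.na(dt$enrollment), "",
                                         dt$enrollment))
  score <- suppressWarnings(as.numeric(dt$rx_risk_score))

  reasons <- character(n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- why
  }
  flag(is.na(dt$patient_id) | dt$patient_id == "", "missing patient_id")
  flag(is.na(birth_date), "unparseable birth_date")
  flag(!sex %in% SEXES, "sex must be M or F")
  flag(!race %in% RACES, "unknown race value")
  flag(!region %in% REGIONS, "unknown region value")
  flag(nchar(enrollment) != 12L,
       "enrollment must hold exactly 12 monthly 0/1 flags")
  flag(!is.na(birth_date) & !is.na(death_date) & death_date < birth_date,
       "death_date precedes birth_date")
  flag(!is.na(score) & score < 0, "rx_risk_score must be nonnegative")

  out <- data.table::data.table(
    patient_id = dt$patient_id, birth_date = birth_date, sex = sex,
    race = race, region = region, enrollment = enrollment,
    death_date = death_date, rx_risk_score = score
  )
  finish_read(out, reasons != "", reasons, "beneficiary summary")
}

#' Construct a code set
#'
#' A named set of (code system, code) entries defining one claims-based
#' indicator, with optional setting restriction (e.g. the walker,
#' wheelchair and specialty-bed indicators only count durable medical
#' equipment claims). `PREFIX` entries match any normalized code starting
#' with the entry's code.
#'
#' @param name indicator name.
#' @param entries data frame with columns `system` (`DX`/`PROC`/`DME`),
#'   `code`, and `match` (`EXACT` or `PREFIX`).
#' @param required_setting optional care-setting filter (one of
#'   `r paste(SETTINGS, collapse = ", ")`).
#' @return a `code_set` object.
#' @export
code_set <- function(name, entries, required_setting = NULL) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) == 0) stopf("code set '%s' has no entries", name)
  need <- c("system", "code", "match")
  if (!all(need %in% names(entries))) {
    stopf("code set '%s': entries need columns %s", name,
          paste(need, collapse = ", "))
  }
  entries$system <- toupper(entries$system)
  entries$match <- toupper(entries$match)
  entries$code <- normalize_code(entries$code)
  if (!all(entries$system %in% CODE_SYSTEMS)) {
    stopf("code set '%s': unknown code_system '%s'", name,
          setdiff(entries$system, CODE_SYSTEMS)[1])
  }
  if (!all(entries$match %in% c("EXACT", "PREFIX"))) {
    stopf("code set '%s': match mode must be EXACT or PREFIX", name)
  }
  if (any(entries$code == "")) stopf("code set '%s': empty code", name)
  if (!is.null(required_setting)) {
    required_setting <- toupper(required_setting)
    if (!required_setting %in% SETTINGS) {
      stopf("code set '%s': unknown required_setting '%s'", name,
            required_setting)
    }
  }
  structure(list(name = name, entries = entries[, need],
                 required_setting = required_setting),
            class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf("<code_set> %s: %d entr%s%s\n", x$name, nrow(x$entries),
              if (nrow(x$entries) == 1) "y" else "ies",
              if (is.null(x$required_setting)) "" else
                paste0(" [setting ", x$required_setting, "]")))
  invisible(x)
}

#' Match medical claims against a code set
#'
#' @param cs a [code_set()].
#' @param code_system,code,setting parallel vectors describing claims
#'   (codes are normalized before comparison).
#' @return logical vector: does each claim match the set?
#' @export
codes_match <- function(cs, code_system, code, setting = NULL) {
  code <- normalize_code(code)
  code_system <- toupper(code_system)
  hit <- rep(FALSE, length(code))
  for (i in seq_len(nrow(cs$entries))) {
    e <- cs$entries[i, ]
    m <- code_system == e$system &
      if (e$match == "EXACT") code == e$code else startsWith(code, e$code)
    hit <- hit | m
  }
  if (!is.null(cs$required_setting) && !is.null(setting)) {
    hit <- hit & toupper(setting) == cs$required_setting
  }
  hit
}

INDICATOR_NAMES <- c("dbs", "fall", "hallucinations", "walker", "wheelchair",
                     "specialty_bed", "dementia", "snf", "hospice")

#' Read indicator code sets from a YAML config
#'
#' Each top-level block names one indicator and lists its code entries,
#' optionally with a `required_setting`. The package ships a default
#' config defining the nine severity indicators
#' (`system.file("extdata", "code_sets.yaml", package = "apdclaims")`);
#' its code lists are illustrative placeholders and are expected to be
#' replaced with locally validated lists.
#'
#' @param path YAML file.
#' @param require_nine require exactly the nine default indicator names
#'   (default `TRUE` for the severity-indicator config; set `FALSE` for
#'   auxiliary sets such as the PD-diagnosis or neurologist definitions).
#' @return named list of [code_set()] objects.
#' @export
read_code_sets <- function(path, require_nine = TRUE) {
  if (!file.exists(path)) stopf("code set file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stopf("code set file %s is empty", path)
  if (anyDuplicated(names(raw))) {
    stopf("duplicate indicator name '%s' in %s",
          names(raw)[duplicated(names(raw))][1], path)
  }
  sets <- lapply(names(raw), function(nm) {
    block <- raw[[nm]]
    entries <- do.call(rbind, lapply(block$entries, function(e) {
      data.frame(system = e$system %||% stop("entry missing 'system'"),
                 code = as.character(e$code %||% stop("entry missing 'code'")),
                 match = e$match %||% "EXACT", stringsAsFactors = FALSE)
    }))
    code_set(nm, entries, required_setting = block$required_setting)
  })
  names(sets) <- names(raw)
  if (require_nine && !setequal(names(sets), INDICATOR_NAMES)) {
    stopf("expected the nine indicator code sets (%s); got: %s",
          paste(INDICATOR_NAMES, collapse = ", "),
          paste(names(sets), collapse = ", "))
  }
  sets
}

#' Write a results table as delimited text
#'
#' Writes any reporting table (classification results, prevalence tables,
#' regression results, the inclusion funnel) as CSV with a header, in a
#' form that round-trips through [read_results()].
#'
#' @param results data frame; must be non-null.
#' @param path output file.
#' @export
write_results <- function(results, path) {
  if (is.null(results)) stopf("results must be non-null")
  results <- as.data.frame(results)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(results, path, dateTimeAs = "ISO")
  invisible(path)
}

#' @rdname write_results
#' @return `read_results()` returns the table as a data.table.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stopf("results file not found: %s", path)
  data.table::fread(path, na.strings = c("", "NA"))
}
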