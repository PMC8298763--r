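# End-to-end wiring: config -> cohort -> dose reconstruction ->
# classification -> indicators -> statistics -> written reports, plus the
# generate/write/read/classify/extract/fit round-trip self-check.

#' Reconstruct dose series for a whole cohort
#'
#' Applies [build_daily_dose()] and [compute_led_series()] per patient.
#'
#' @param pharmacy_claims claims table (many patients).
#' @param ref drug reference table.
#' @param period a [study_period()].
#' @param overlap_policy,lookback see [build_daily_dose()].
#' @param patient_ids patients to cover; those without any claims get
#'   all-zero series. Default: patients present in the claims.
#' @return named list of [dose_series()], one per patient.
#' @export
cohort_dose_series <- function(pharmacy_claims, ref,
                               period = study_period(),
                               overlap_policy = c("push_forward",
                                                  "sum_overlap"),
                               lookback = FALSE, patient_ids = NULL) {
  overlap_policy <- match.arg(overlap_policy)
  rx <- data.table::as.data.table(pharmacy_claims)
  patient_ids <- as.character(patient_ids %||% sort(unique(rx$patient_id)))
  rx <- rx[patient_id %in% patient_ids]
  by_patient <- split(rx, by = "patient_id")
  out <- vector("list", length(patient_ids))
  names(out) <- patient_ids
  zero <- rep(0, period$n_days)
  for (pid in patient_ids) {
    claims <- by_patient[[pid]]
    if (is.null(claims) || nrow(claims) == 0) {
      out[[pid]] <- dose_series(pid, period, zero, zero)
    } else {
      dose <- suppressMessages(
        build_daily_dose(claims, ref, period, overlap_policy, lookback))
      out[[pid]] <- compute_led_series(dose, ref, pid, period)
    }
  }
  out
}

#' Assemble a pipeline run configuration
#'
#' @param beneficiaries,pharmacy_claims,medical_claims paths to the input
#'   tables.
#' @param out_dir directory the run writes its artifacts into (created if
#'   needed); inputs are never modified.
#' @param code_sets path to the nine-indicator code-set YAML (default:
#'   the shipped illustrative config).
#' @param neurologist_code_sets path to a YAML whose `neurologist` block
#'   defines the visit code set.
#' @param drug_reference path to the LED conversion YAML.
#' @param period a [study_period()].
#' @param rules character vector of rule names to classify under.
#' @param overlap_policy,lookback see [build_daily_dose()].
#' @param verbose emit stage messages to stderr.
#' @return a `run_config` object.
#' @export
run_config <- function(beneficiaries, pharmacy_claims, medical_claims,
                       out_dir,
                       code_sets = system.file("extdata", "code_sets.yaml",
                                               package = "apdclaims"),
                       neurologist_code_sets =
                         system.file("extdata", "synthetic_code_sets.yaml",
                                     package = "apdclaims"),
                       drug_reference = default_drug_reference(),
                       period = study_period(),
                       rules = RULE_NAMES,
                       overlap_policy = "push_forward",
                       lookback = FALSE, verbose = TRUE) {
  paths <- c(beneficiaries = beneficiaries,
             pharmacy_claims = pharmacy_claims,
             medical_claims = medical_claims, code_sets = code_sets,
             neurologist_code_sets = neurologist_code_sets,
             drug_reference = drug_reference)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stopf("input path(s) do not exist: %s",
          paste(sprintf("%s (%s)", names(missing), missing),
                collapse = ", "))
  }
  if (length(rules) < 1) stopf("select at least one dosing rule")
  structure(list(paths = as.list(paths), out_dir = out_dir,
                 period = period, rules = rules,
                 overlap_policy = overlap_policy, lookback = lookback,
                 verbose = verbose),
            class = "run_config")
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[apdclaims] stage: ", name)
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full claims pipeline
#'
#' Reads the input tables, applies the inclusion criteria, reconstructs
#' dose series, classifies patients under the configured rules, extracts
#' the nine indicators, and writes six artifacts into `out_dir`:
#' `inclusion_funnel.csv`, `classifications.csv`, `descriptives.csv`,
#' `prevalence.csv`, `regressions.csv` and `run_metadata.yaml`. Reruns
#' with identical config and inputs produce identical artifact contents.
#'
#' @param config a [run_config()].
#' @return (invisibly) named vector of the written artifact paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stopf("config must be a run_config")
  v <- config$verbose
  p <- config$paths
  period <- config$period

  ben <- stage("read beneficiaries", v, read_beneficiaries(p$beneficiaries))
  rx <- stage("read pharmacy claims", v,
              read_pharmacy_claims(p$pharmacy_claims))
  med <- stage("read medical claims", v,
               read_medical_claims(p$medical_claims))
  sets <- stage("read code sets", v, {
    all_sets <- read_code_sets(p$code_sets, require_nine = FALSE)
    missing_sets <- setdiff(INDICATOR_NAMES, names(all_sets))
    if (length(missing_sets) > 0) {
      stopf("code set file lacks indicator(s): %s",
            paste(missing_sets, collapse = ", "))
    }
    all_sets[INDICATOR_NAMES]
  })
  neuro <- stage("read neurologist code set", v,
                 read_code_sets(p$neurologist_code_sets,
                                require_nine = FALSE)$neurologist)
  if (is.null(neuro)) stopf("neurologist code set not found in %s",
                            p$neurologist_code_sets)
  ref <- stage("read drug reference", v, read_drug_reference(p$drug_reference))

  inc <- stage("inclusion criteria", v,
               apply_inclusion_criteria(ben, med, rx, period = period,
                                        ref = ref))
  included <- inc$included
  if (length(included) == 0) stopf("no patients survive inclusion")
  ben_inc <- ben[ben$patient_id %in% included, ]

  covs <- stage("covariates", v,
                build_covariates(ben_inc, med, neuro, period))
  series <- stage("dose reconstruction", v,
                  cohort_dose_series(rx, ref, period,
                                     config$overlap_policy, config$lookback,
                                     patient_ids = included))
  rules <- lapply(config$rules, dosing_rule)
  cls <- stage("classification", v, classify_cohort(series, rules))
  profiles <- stage("indicators", v,
                    extract_indicators(med, sets, period,
                                       patient_ids = included))
  desc <- stage("descriptives", v,
                describe_cohort(covs, cls, rule = config$rules[1]))
  prev <- stage("prevalence", v,
                indicator_prevalence(profiles, cls, rule = config$rules[1]))
  regs <- stage("regressions", v, fit_all(profiles, cls, covs))

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- c(
    inclusion_funnel = file.path(out, "inclusion_funnel.csv"),
    classifications = file.path(out, "classifications.csv"),
    descriptives = file.path(out, "descriptives.csv"),
    prevalence = file.path(out, "prevalence.csv"),
    regressions = file.path(out, "regressions.csv")
  )
  write_results(as.data.frame(inc$report), artifacts["inclusion_funnel"])
  write_results(cls, artifacts["classifications"])
  write_results(desc, artifacts["descriptives"])
  write_results(prev, artifacts["prevalence"])
  write_results(regs, artifacts["regressions"])

  meta <- list(
    package = "apdclaims",
    version = as.character(utils::packageVersion("apdclaims")),
    input_md5 = as.list(tools::md5sum(unlist(p))),
    period = list(start = format(period$start_date),
                  end = format(period$end_date)),
    rules = config$rules,
    overlap_policy = config$overlap_policy,
    rows = list(beneficiaries = nrow(ben), pharmacy_claims = nrow(rx),
                medical_claims = nrow(med),
                included = length(included)),
    apd_fraction = as.list(apd_fraction(cls))
  )
  meta_path <- file.path(out, "run_metadata.yaml")
  yaml::write_yaml(meta, meta_path)
  artifacts <- c(artifacts, run_metadata = meta_path)
  if (v) message("[apdclaims] wrote ", length(artifacts), " artifacts to ",
                 out)
  invisible(artifacts)
}

#' Generate-write-read-classify-extract-fit round trip
#'
#' Self-check for the whole stack: generates a synthetic cohort, writes
#' and re-reads the delimited tables, runs inclusion, dose
#' reconstruction, classification, indicator extraction and the adjusted
#' regressions, then compares every stage with the generator's ground
#' truth.
#'
#' @param config a [synthetic_config()].
#' @param dir scratch directory for the written tables.
#' @param agreement_floor minimum classifier/latent-label agreement among
#'   included patients.
#' @param coverage_min minimum number of the nine fitted 95% CIs that
#'   must cover their configured true odds ratio.
#' @return a `roundtrip_report` list: per-stage status, the funnel
#'   comparison, agreement, assigned APD fraction, the odds-ratio
#'   recovery table and an overall `pass` flag.
#' @export
roundtrip_check <- function(config, dir = tempfile("apdclaims_rt_"),
                            agreement_floor = 0.99, coverage_min = 7L) {
  report <- list(stages = character(), pass = FALSE)
  class(report) <- "roundtrip_report"
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stopf("round-trip stage '%s' failed: %s", name, conditionMessage(e))
    })
    report$stages <<- c(report$stages, name)
    res
  }

  cohort <- run_stage("generate", generate_cohort(config))
  paths <- run_stage("write", write_cohort(cohort, dir))
  ben <- run_stage("read", read_beneficiaries(paths["beneficiaries"]))
  rx <- suppressMessages(read_pharmacy_claims(paths["pharmacy_claims"]))
  med <- read_medical_claims(paths["medical_claims"])
  ref <- read_drug_reference()
  period <- config$period

  inc <- run_stage("inclusion",
                   apply_inclusion_criteria(ben, med, rx, period = period,
                                            ref = ref))
  gt <- cohort$ground_truth
  expected <- with(gt, {
    n <- length(patient_id)
    drop <- function(modes) sum(exclusion_mode %in% modes)
    c(n, n,
      n - drop("under_65"),
      n - drop(c("under_65", "enrollment_gap")),
      n - drop(c("under_65", "enrollment_gap", "died")),
      n - drop(c("under_65", "enrollment_gap", "died", "no_levodopa")),
      n - drop(EXCLUSION_MODES))
  })
  report$funnel <- data.frame(inc$report,
                              expected = expected,
                              matches = inc$report$n_remaining == expected)
  report$funnel_matches <- all(report$funnel$matches)

  series <- run_stage("dose reconstruction",
                      cohort_dose_series(rx, ref, period,
                                         patient_ids = inc$included))
  cls <- run_stage("classify",
                   classify_cohort(series, dosing_rules()["LED_GT_1000"]))
  latent <- gt$latent_apd[match(cls$patient_id, gt$patient_id)]
  report$agreement <- mean(cls$is_apd == latent)
  report$apd_fraction <- mean(cls$is_apd)

  profiles <- run_stage("extract",
                        extract_indicators(med, synthetic_code_sets(),
                                           period,
                                           patient_ids = inc$included))
  gti <- gt[match(profiles$patient_id, gt$patient_id)]
  report$indicator_agreement <- mean(vapply(
    INDICATOR_NAMES, function(nm) mean(profiles[[nm]] == gti[[nm]]), 0))

  covs <- run_stage("covariates",
                    build_covariates(ben[ben$patient_id %in% inc$included, ],
                                     med, synthetic_neurologist_code_set(),
                                     period))
  fits <- run_stage("fit", fit_all(profiles, cls, covs))
  truth <- config$indicators
  fits$true_or <- truth$true_or[match(fits$indicator, truth$name)]
  fits$ci_covers_truth <- fits$ci_low <= fits$true_or &
    fits$true_or <= fits$ci_high
  report$or_recovery <- fits
  report$or_coverage <- sum(fits$ci_covers_truth)

  report$pass <- report$funnel_matches &&
    report$agreement >= agreement_floor &&
    report$indicator_agreement == 1 &&
    report$or_coverage >= coverage_min
  report
}

#' @export
print.roundtrip_report <- function(x, ...) {
  cat(sprintf("<roundtrip_report> %s\n",
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  stages run: %s\n", paste(x$stages, collapse = " -> ")))
  cat(sprintf("  funnel matches bookkeeping: %s\n", x$funnel_matches))
  cat(sprintf("  classifier/latent agreement: %.4f\n", x$agreement))
  cat(sprintf("  assigned APD fraction: %.3f\n", x$apd_fraction))
  cat(sprintf("  indicator extraction agreement: %.4f\n",
              x$indicator_agreement))
  cat(sprintf("  true-OR coverage: %d/9 CIs\n", x$or_coverage))
  invisible(x)
}
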