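# Synthetic claims-cohort generator with known ground truth. Emits the
# same delimited-text tables the readers consume (beneficiary summary,
# pharmacy claims, medical claims) so the whole pipeline — dose
# reconstruction, classification, inclusion funnel, indicator extraction,
# regression — is exercised end to end without access to real claims.
#
# Dose trajectories are built from realistic dispensing events (30-day
# supplies refilled with a few days of jitter), not from directly emitted
# daily series, so the reconstruction engine is genuinely exercised.
# Latent severity is drawn first; advanced patients receive levodopa fill
# sequences whose reconstructed 30-day mean LED exceeds 1000 mg/day for at
# least one window, mild patients' trajectories stay at or below it, by
# construction. Indicators are drawn from per-indicator logistic models
# with configured odds ratios on the latent label.

EXCLUSION_MODES <- c("under_65", "enrollment_gap", "died", "no_levodopa",
                     "missing_race")

default_indicator_models <- function() {
  # baseline prevalence: typical mild-moderate rates for a Medicare PD
  # cohort; true OR: defaults in the range reported for these indicators
  data.frame(
    name = INDICATOR_NAMES,
    baseline_prev = c(0.016, 0.054, 0.028, 0.054, 0.084, 0.052, 0.392,
                      0.002, 0.017),
    true_or = c(2.96, 1.27, 1.71, 1.58, 2.02, 2.15, 1.21, 1.72, 1.71),
    stringsAsFactors = FALSE
  )
}

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of an aged fee-for-service
#' Medicare PD cohort: one calendar year of Part D-style dispensing
#' events, age/sex/race/region marginals, an RxHCC-style risk score with
#' mean 1.48 (SD 0.46) clamped to \[0.72, 6.30\], group-specific
#' neurologist-visit prevalence, and per-indicator logistic models. They
#' are presentation defaults describing a plausible cohort, not estimates
#' of the Medicare population.
#'
#' @param n_patients number of patients to generate.
#' @param seed integer RNG seed; generation is fully deterministic given
#'   the seed.
#' @param apd_fraction target share of latent advanced-disease
#'   trajectories.
#' @param excludable_fraction share of patients deliberately failing one
#'   inclusion criterion (spread over under-65, an enrollment gap, death
#'   during the year, no levodopa claim, missing race) to exercise the
#'   attrition funnel.
#' @param period a [study_period()].
#' @param marginals named list of probability vectors for `age`
#'   (`r paste(AGE_BANDS, collapse = ", ")`), `sex` (M/F), `race`, and
#'   `region`.
#' @param risk_score list with `mean`, `sd`, `min`, `max` for the comorbidity
#'   risk score.
#' @param neurologist named vector: visit probability for
#'   `mild_moderate` and `apd` patients.
#' @param indicators data frame with `name`, `baseline_prev`, `true_or`
#'   (odds ratio on the latent advanced label).
#' @param age_log_or additive log-odds per age band above 65-69 in the
#'   indicator models (a mild covariate effect, so adjustment matters).
#' @param dose list of trajectory parameters: `mild_levodopa_range` and
#'   `apd_levodopa_range` (mg/day drawn uniformly per patient),
#'   `agonist_prob` and `agonist_led_range` (dopamine-agonist add-on, in
#'   LED mg/day), `comt_prob_apd` (entacapone add-on among advanced
#'   patients), `fill_days` (supply per fill) and `jitter_days` (uniform
#'   refill jitter).
#' @return a validated `synthetic_config` object.
#' @export
synthetic_config <- function(
    n_patients,
    seed = 1L,
    apd_fraction = 0.2,
    excludable_fraction = 0.1,
    period = study_period(),
    marginals = list(
      age = c(`65_69` = 0.115, `70_74` = 0.193, `75_79` = 0.229,
              GE_80 = 0.463),
      sex = c(M = 0.485, F = 0.515),
      race = c(WHITE = 0.876, BLACK = 0.046, OTHER = 0.077),
      region = c(NORTHEAST = 0.196, MIDWEST = 0.267, SOUTH = 0.365,
                 WEST = 0.171)
    ),
    risk_score = list(mean = 1.48, sd = 0.46, min = 0.72, max = 6.30),
    neurologist = c(mild_moderate = 0.663, apd = 0.842),
    indicators = default_indicator_models(),
    age_log_or = log(1.1),
    dose = list(mild_levodopa_range = c(300, 600),
                apd_levodopa_range = c(1200, 1500),
                agonist_prob = 0.4, agonist_led_range = c(150, 300),
                comt_prob_apd = 0.3, fill_days = 30L, jitter_days = 3L),
    threshold_mg = 1000) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) {
    stopf("n_patients must be a positive integer")
  }
  if (apd_fraction < 0 || apd_fraction > 1 ||
      excludable_fraction < 0 || excludable_fraction > 1) {
    stopf("fractions must lie in [0, 1]")
  }
  for (v in names(marginals)) {
    p <- marginals[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 0.02) {
      stopf("marginals for '%s' must be nonnegative and sum to 1", v)
    }
    marginals[[v]] <- p / sum(p)
  }
  if (any(neurologist < 0 | neurologist > 1)) {
    stopf("neurologist prevalences must lie in [0, 1]")
  }
  if (any(indicators$true_or <= 0)) stopf("true odds ratios must be > 0")
  if (any(indicators$baseline_prev <= 0 | indicators$baseline_prev >= 1)) {
    stopf("baseline prevalences must lie in (0, 1)")
  }
  if (!setequal(indicators$name, INDICATOR_NAMES)) {
    stopf("indicator models must cover exactly the nine indicators")
  }
  fd <- dose$fill_days
  jd <- dose$jitter_days
  if (jd >= fd) stopf("jitter_days must be smaller than fill_days")
  # feasibility: worst-case advanced window (one full supply at the low
  # end of the range) must still clear the threshold, and the richest
  # mild trajectory must stay below it (2 mg/day slack for quantity
  # rounding on each channel)
  if (min(dose$apd_levodopa_range) - 2 <= threshold_mg) {
    stopf("infeasible config: advanced daily levodopa (min %g) must exceed %s",
          min(dose$apd_levodopa_range),
          sprintf("the %g mg/day threshold", threshold_mg))
  }
  mild_max <- max(dose$mild_levodopa_range) + max(dose$agonist_led_range)
  if (mild_max + 4 > threshold_mg) {
    stopf("infeasible config: mild LED can reach %g mg/day, above the %g %s",
          mild_max, threshold_mg, "mg/day threshold")
  }
  structure(
    list(n_patients = n_patients, seed = as.integer(seed),
         apd_fraction = apd_fraction,
         excludable_fraction = excludable_fraction, period = period,
         marginals = marginals, risk_score = risk_score,
         neurologist = neurologist, indicators = indicators,
         age_log_or = age_log_or, dose = dose, threshold_mg = threshold_mg),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config> %d patients, seed %d, ",
                     "APD fraction %.2f, excludable %.2f\n"),
              x$n_patients, x$seed, x$apd_fraction, x$excludable_fraction))
  invisible(x)
}

#' Synthetic test code sets
#'
#' Code sets built from clearly synthetic codes (prefixed `S`), used by
#' the generator and the test-suite so that validation never depends on
#' the illustrative real-code defaults. Shipped at
#' `system.file("extdata", "synthetic_code_sets.yaml",
#' package = "apdclaims")`.
#'
#' @return `synthetic_code_sets()`: named list of the nine indicator
#'   [code_set()]s; `synthetic_neurologist_code_set()`: the visit set.
#' @export
synthetic_code_sets <- function() {
  path <- system.file("extdata", "synthetic_code_sets.yaml",
                      package = "apdclaims")
  sets <- read_code_sets(path, require_nine = FALSE)
  sets[INDICATOR_NAMES]
}

#' @rdname synthetic_code_sets
#' @export
synthetic_neurologist_code_set <- function() {
  path <- system.file("extdata", "synthetic_code_sets.yaml",
                      package = "apdclaims")
  read_code_sets(path, require_nine = FALSE)$neurologist
}

# sample matching (system, code, setting) triples from a code set
sample_set_codes <- function(cs, n) {
  if (n == 0L) {
    return(data.frame(code_system = character(), code = character(),
                      setting = character()))
  }
  i <- sample.int(nrow(cs$entries), n, replace = TRUE)
  e <- cs$entries[i, , drop = FALSE]
  code <- ifelse(e$match == "PREFIX",
                 paste0(e$code, sample(0:9, n, replace = TRUE)), e$code)
  setting <- if (!is.null(cs$required_setting)) {
    rep(cs$required_setting, n)
  } else {
    sample(c("OUTPATIENT", "INPATIENT"), n, replace = TRUE,
           prob = c(0.8, 0.2))
  }
  data.frame(code_system = e$system, code = code, setting = setting,
             stringsAsFactors = FALSE)
}

# fill schedules for all n patients at once: first fill in the opening
# days of the period, then one refill per cycle with uniform jitter
fill_schedule <- function(n, n_days, fill_days, jitter_days) {
  m <- ceiling(n_days / (fill_days - jitter_days)) + 1L
  start <- sample.int(5L, n, replace = TRUE)
  gaps <- matrix(fill_days + sample.int(2L * jitter_days + 1L,
                                        n * (m - 1L), replace = TRUE) -
                   jitter_days - 1L, nrow = n)
  days <- matrix(0L, nrow = n, ncol = m)
  days[, 1] <- start
  for (k in 2:m) days[, k] <- days[, k - 1L] + gaps[, k - 1L]
  days
}

schedule_claims <- function(days, patients, drug_id, quantity, days_supply,
                            strength, period) {
  keep <- which(days <= period$n_days, arr.ind = TRUE)
  i <- keep[, 1]
  data.table::data.table(
    patient_id = patients[i],
    drug_id = drug_id,
    fill_date = period$start_date + (days[keep] - 1L),
    days_supply = days_supply,
    quantity = quantity[i],
    strength_mg = strength
  )
}

# daily coverage vector for one drug's stockpile-forward fill schedule:
# per-patient bookkeeping used only for ground truth
daily_coverage <- function(days, rate, n_days, days_supply) {
  daily <- numeric(n_days)
  prev_end <- -.Machine$integer.max
  for (d in days[days <= n_days]) {
    start <- max(d, prev_end + 1L)
    end <- start + days_supply - 1L
    lo <- max(start, 1L)
    hi <- min(end, n_days)
    if (lo <= hi) daily[lo:hi] <- daily[lo:hi] + rate
    prev_end <- max(prev_end, end)
  }
  daily
}

#' Generate a synthetic claims cohort
#'
#' Draws latent severity labels, builds dispensing schedules whose
#' reconstructed dose trajectories separate the two severity strata at
#' the configured threshold, emits medical claims for the PD diagnosis,
#' neurologist visits and the nine indicators (from logistic models with
#' the configured odds ratios), and writes a ground-truth record for every
#' patient. Generation uses R's Mersenne-Twister generator and is
#' byte-deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param code_sets indicator code sets the generator draws claim codes
#'   from; default [synthetic_code_sets()].
#' @param neurologist_codeset code set for neurologist-visit claims.
#' @return list with `beneficiaries`, `pharmacy_claims`,
#'   `medical_claims` (data.tables in the canonical reader schemas),
#'   `ground_truth` (per-patient latent label, exclusion bookkeeping,
#'   target daily doses, true max 30-day LED, indicator draws) and
#'   `indicator_model` (the coefficients used).
#' @export
generate_cohort <- function(config,
                            code_sets = synthetic_code_sets(),
                            neurologist_codeset =
                              synthetic_neurologist_code_set()) {
  if (!inherits(config, "synthetic_config")) {
    stopf("config must come from synthetic_config()")
  }
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  n <- config$n_patients
  period <- config$period
  n_days <- period$n_days
  ids <- sprintf("P%06d", seq_len(n))

  latent_apd <- runif(n) < config$apd_fraction
  excluded <- runif(n) < config$excludable_fraction
  mode <- rep("none", n)
  mode[excluded] <- sample(EXCLUSION_MODES, sum(excluded), replace = TRUE)

  ## --- beneficiaries -----------------------------------------------------
  age_band_draw <- sample(AGE_BANDS, n, replace = TRUE,
                          prob = config$marginals$age)
  age <- c(`65_69` = 65L, `70_74` = 70L, `75_79` = 75L,
           GE_80 = 80L)[age_band_draw] +
    sample.int(5L, n, replace = TRUE) - 1L
  age[age_band_draw == "GE_80"] <- 80L + sample.int(15L, sum(age_band_draw ==
                                                              "GE_80"),
                                                    replace = TRUE) - 1L
  age[mode == "under_65"] <- 60L + sample.int(5L, sum(mode == "under_65"),
                                              replace = TRUE) - 1L
  anchor <- as.Date(sprintf("%d-01-01",
                            as.POSIXlt(period$start_date)$year + 1900L - age))
  birth_date <- anchor - (sample.int(365L, n, replace = TRUE) - 1L)

  sex <- sample(names(config$marginals$sex), n, replace = TRUE,
                prob = config$marginals$sex)
  race <- sample(names(config$marginals$race), n, replace = TRUE,
                 prob = config$marginals$race)
  race[mode == "missing_race"] <- "MISSING"
  region <- sample(names(config$marginals$region), n, replace = TRUE,
                   prob = config$marginals$region)

  enrollment <- rep(strrep("1", 12L), n)
  gap_month <- sample.int(12L, n, replace = TRUE)
  has_gap <- mode == "enrollment_gap"
  enrollment[has_gap] <- vapply(gap_month[has_gap], function(m) {
    f <- rep("1", 12L); f[m] <- "0"; paste(f, collapse = "")
  }, "")

  death_date <- rep(as.Date(NA), n)
  died <- mode == "died"
  death_date[died] <- period$start_date + 30L +
    sample.int(n_days - 40L, sum(died), replace = TRUE)

  rs <- config$risk_score
  score <- pmin(pmax(rnorm(n, rs$mean, rs$sd), rs$min), rs$max)

  beneficiaries <- data.table::data.table(
    patient_id = ids, birth_date = birth_date, sex = sex, race = race,
    region = region, enrollment = enrollment, death_date = death_date,
    rx_risk_score = round(score, 3)
  )

  ## --- pharmacy claims ---------------------------------------------------
  d <- config$dose
  ld_rate_target <- ifelse(latent_apd,
                           runif(n, d$apd_levodopa_range[1],
                                 d$apd_levodopa_range[2]),
                           runif(n, d$mild_levodopa_range[1],
                                 d$mild_levodopa_range[2]))
  ld_qty <- pmax(1, round(d$fill_days * ld_rate_target / 100))
  ld_rate <- ld_qty * 100 / d$fill_days
  ld_days <- fill_schedule(n, n_days, d$fill_days, d$jitter_days)

  has_agonist <- runif(n) < d$agonist_prob
  ag_led_target <- runif(n, d$agonist_led_range[1], d$agonist_led_range[2])
  ag_qty <- pmax(1, round(d$fill_days * (ag_led_target / 100) / 0.5))
  ag_led <- ag_qty * 0.5 * 100 / d$fill_days   # pramipexole, LED factor 100
  ag_days <- fill_schedule(n, n_days, d$fill_days, d$jitter_days)

  has_comt <- latent_apd & runif(n) < d$comt_prob_apd
  comt_qty <- rep(90, n)                       # entacapone 200 mg, 3/day
  comt_days <- fill_schedule(n, n_days, d$fill_days, d$jitter_days)

  takes_levodopa <- mode != "no_levodopa"
  rx <- data.table::rbindlist(list(
    schedule_claims(ld_days[takes_levodopa, , drop = FALSE],
                    ids[takes_levodopa], "levodopa_ir",
                    ld_qty[takes_levodopa], d$fill_days, 100, period),
    schedule_claims(ag_days[has_agonist, , drop = FALSE], ids[has_agonist],
                    "pramipexole", ag_qty[has_agonist], d$fill_days, 0.5,
                    period),
    schedule_claims(comt_days[has_comt, , drop = FALSE], ids[has_comt],
                    "entacapone", comt_qty[has_comt], d$fill_days, 200,
                    period)
  ))
  data.table::setorder(rx, patient_id, drug_id, fill_date)

  ## --- medical claims ----------------------------------------------------
  med_parts <- list()
  rdate <- function(k) period$start_date + sample.int(n_days, k,
                                                      replace = TRUE) - 1L
  # PD diagnosis claim for everyone (outpatient)
  med_parts$pd <- data.table::data.table(
    patient_id = ids, service_date = rdate(n), code_system = "DX",
    code = "3320", setting = "OUTPATIENT"
  )
  # neurologist visits by latent group
  p_neuro <- ifelse(latent_apd, config$neurologist[["apd"]],
                    config$neurologist[["mild_moderate"]])
  has_neuro <- runif(n) < p_neuro
  k <- sum(has_neuro)
  nc <- sample_set_codes(neurologist_codeset, k)
  med_parts$neuro <- data.table::data.table(
    patient_id = ids[has_neuro], service_date = rdate(k),
    code_system = nc$code_system, code = nc$code, setting = "OUTPATIENT"
  )
  # indicators from logistic models on the latent label + age trend
  age_step <- as.integer(factor(age_band_draw, levels = AGE_BANDS)) - 1L
  age_step[mode == "under_65"] <- 0L
  im <- config$indicators
  ind_hits <- matrix(FALSE, nrow = n, ncol = length(INDICATOR_NAMES),
                     dimnames = list(NULL, INDICATOR_NAMES))
  for (j in seq_len(nrow(im))) {
    nm <- im$name[j]
    eta <- qlogis(im$baseline_prev[j]) + log(im$true_or[j]) * latent_apd +
      config$age_log_or * age_step
    hit <- runif(n) < plogis(eta)
    ind_hits[, nm] <- hit
    k <- sum(hit)
    cc <- sample_set_codes(code_sets[[nm]], k)
    med_parts[[nm]] <- data.table::data.table(
      patient_id = ids[hit], service_date = rdate(k),
      code_system = cc$code_system, code = cc$code, setting = cc$setting
    )
  }
  med <- data.table::rbindlist(med_parts)
  data.table::setorder(med, patient_id, service_date, code_system, code)

  ## --- ground truth ------------------------------------------------------
  comt_led_add <- ifelse(has_comt & takes_levodopa, 0.33 * ld_rate, 0)
  target_led <- ifelse(takes_levodopa, ld_rate, 0) +
    ifelse(has_agonist, ag_led, 0) + comt_led_add
  true_max_led <- vapply(seq_len(n), function(i) {
    led <- numeric(n_days)
    if (takes_levodopa[i]) {
      ld <- daily_coverage(ld_days[i, ], ld_rate[i], n_days, d$fill_days)
      led <- ld
      if (has_comt[i]) {
        on <- daily_coverage(comt_days[i, ], 1, n_days, d$fill_days) > 0
        led <- led + 0.33 * ld * on
      }
    }
    if (has_agonist[i]) {
      led <- led + daily_coverage(ag_days[i, ], ag_led[i], n_days,
                                  d$fill_days)
    }
    max(rolling_window_average(led, 30L))
  }, 0)

  ground_truth <- data.table::data.table(
    patient_id = ids, latent_apd = latent_apd, excluded = excluded,
    exclusion_mode = mode,
    target_daily_levodopa = ifelse(takes_levodopa, ld_rate, 0),
    target_daily_led = target_led, true_max_led = true_max_led,
    neurologist_visit = has_neuro
  )
  for (nm in INDICATOR_NAMES) ground_truth[[nm]] <- ind_hits[, nm]

  list(beneficiaries = beneficiaries, pharmacy_claims = rx,
       medical_claims = med, ground_truth = ground_truth,
       indicator_model = data.frame(
         name = im$name, baseline_prev = im$baseline_prev,
         log_or = log(im$true_or), age_log_or = config$age_log_or,
         generator = "apdclaims-synthetic-1",
         stringsAsFactors = FALSE),
       config = config)
}

#' Write a generated cohort as delimited-text tables
#'
#' Emits `beneficiaries.csv`, `pharmacy_claims.csv`, `medical_claims.csv`
#' (the canonical reader schemas) plus `ground_truth.csv`, which the
#' pipeline itself never reads.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    beneficiaries = file.path(dir, "beneficiaries.csv"),
    pharmacy_claims = file.path(dir, "pharmacy_claims.csv"),
    medical_claims = file.path(dir, "medical_claims.csv"),
    ground_truth = file.path(dir, "ground_truth.csv")
  )
  for (nm in names(paths)) write_results(cohort[[nm]], paths[[nm]])
  paths
}
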