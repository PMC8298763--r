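# Fixtures are built in code: a small in-memory drug reference, writers
# for the delimited tables, and independent brute-force oracles for the
# rolling mean, the window classifier and the pill-stock dose
# reconstruction.

tiny_ref <- function() {
  data.frame(
    drug_id = c("levodopa_ir", "levodopa_cr", "agonist_x", "comt_x",
                "maob_x"),
    drug_class = c("LEVODOPA_IR", "LEVODOPA_CR", "DOPAMINE_AGONIST",
                   "COMT_ADJUNCT", "MAOB"),
    led_factor = c(1, 0.75, 100, NA, 10),
    comt_multiplier = c(NA, NA, NA, 0.33, NA),
    counts_as_levodopa = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

pharmacy_claims_df <- function(patient_id, drug_id, fill_date, days_supply,
                               quantity, strength_mg) {
  data.frame(patient_id = patient_id, drug_id = drug_id,
             fill_date = as.Date(fill_date),
             days_supply = as.integer(days_supply), quantity = quantity,
             strength_mg = strength_mg, stringsAsFactors = FALSE)
}

beneficiary_df <- function(patient_id, birth_date = "1940-01-01",
                           sex = "F", race = "WHITE", region = "SOUTH",
                           enrollment = strrep("1", 12),
                           death_date = NA, rx_risk_score = 1.5) {
  data.frame(patient_id = patient_id, birth_date = as.Date(birth_date),
             sex = sex, race = race, region = region,
             enrollment = enrollment,
             death_date = as.Date(death_date),
             rx_risk_score = rx_risk_score, stringsAsFactors = FALSE)
}

medical_claims_df <- function(patient_id, service_date, code_system, code,
                              setting = "OUTPATIENT") {
  data.frame(patient_id = patient_id, service_date = as.Date(service_date),
             code_system = code_system, code = normalize_code(code),
             setting = setting, stringsAsFactors = FALSE)
}

write_tmp_csv <- function(df, lines = NULL) {
  path <- tempfile(fileext = ".csv")
  if (is.null(lines)) {
    data.table::fwrite(df, path, dateTimeAs = "ISO")
  } else {
    writeLines(lines, path)
  }
  path
}

make_series <- function(levodopa, led = levodopa, patient_id = "p1",
                        period = study_period()) {
  if (length(levodopa) == 1) levodopa <- rep(levodopa, period$n_days)
  if (length(led) == 1) led <- rep(led, period$n_days)
  dose_series(patient_id, period, levodopa, led)
}

# O(n * w) brute-force rolling mean
brute_roll <- function(x, w) {
  vapply(seq_len(length(x) - w + 1L),
         function(i) mean(x[i:(i + w - 1L)]), 0)
}

# brute-force classifier: explicitly averages every window
oracle_classify <- function(series, rule) {
  x <- if (rule$channel == "LED") series$led_mg else series$levodopa_mg
  means <- brute_roll(x, rule$window_days)
  hit <- if (rule$strict) means > rule$threshold_mg else
    means >= rule$threshold_mg
  list(is_apd = any(hit), max_mean = max(means),
       first = if (any(hit)) which(hit)[1] else NA_integer_)
}

# event-driven pill-stock oracle for push-forward reconstruction of one
# drug: a queue of fills, one day of supply consumed per calendar day
pill_stock_oracle <- function(fill_day, days_supply, rate, n_days) {
  daily <- numeric(n_days)
  queue_days <- integer(0)
  queue_rate <- numeric(0)
  horizon <- n_days + sum(days_supply) + max(c(fill_day, 1L))
  for (day in seq_len(horizon)) {
    arriving <- which(fill_day == day)
    for (i in arriving) {
      queue_days <- c(queue_days, days_supply[i])
      queue_rate <- c(queue_rate, rate[i])
    }
    if (length(queue_days) > 0) {
      if (day >= 1 && day <= n_days) daily[day] <- queue_rate[1]
      queue_days[1] <- queue_days[1] - 1L
      if (queue_days[1] == 0L) {
        queue_days <- queue_days[-1]
        queue_rate <- queue_rate[-1]
      }
    }
  }
  daily
}

# random daily dose series whose window means straddle the 800/1000
# thresholds, with LED >= levodopa
random_series <- function(patient_id = "p1", n_days = 365L) {
  n_seg <- sample(3:8, 1)
  bounds <- sort(sample(2:(n_days - 1), n_seg - 1))
  lens <- diff(c(0, bounds, n_days))
  levodopa <- unlist(mapply(function(l, v) rep(v, l), lens,
                            runif(n_seg, 0, 1400), SIMPLIFY = FALSE))
  led <- levodopa + unlist(mapply(function(l, v) rep(v, l), lens,
                                  runif(n_seg, 0, 400), SIMPLIFY = FALSE))
  make_series(levodopa, led, patient_id = patient_id)
}
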