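period <- study_period()
sets <- synthetic_code_sets()

test_that("indicator extraction matches codes, settings and the period", {
  # zero claims -> all nine false, no dates
  prof <- extract_indicators(medical_claims_df(character(), as.Date(NULL),
                                               character(), character(),
                                               character()),
                             sets, period, patient_ids = "p1")
  expect_true(all(!unlist(prof[names(sets)])))
  expect_true(all(is.na(unlist(prof[paste0(names(sets), "_first_date")]))))

  # one walker DME claim -> walker only
  med <- medical_claims_df("p1", "2013-04-01", "DME", "SWALK1", "DME")
  prof <- extract_indicators(med, sets, period)
  expect_true(prof$walker)
  expect_equal(sum(unlist(prof[names(sets)])), 1)
  expect_equal(prof$walker_first_date, as.Date("2013-04-01"))

  # same code in the wrong setting does not count
  med2 <- medical_claims_df("p1", "2013-04-01", "DME", "SWALK1",
                            "OUTPATIENT")
  expect_false(extract_indicators(med2, sets, period)$walker)

  # unmatched code -> all false; out-of-period claim ignored
  expect_false(any(unlist(extract_indicators(
    medical_claims_df("p1", "2013-04-01", "DX", "ZZZ"),
    sets, period)[names(sets)])))
  expect_false(extract_indicators(
    medical_claims_df("p1", "2014-04-01", "DME", "SWALK1", "DME"),
    sets, period, patient_ids = "p1")$walker)

  # earliest matching date is kept, prefix codes match
  med3 <- medical_claims_df("p1", c("2013-09-09", "2013-02-02"), "DX",
                            c("SDEM1", "SDEM9"))
  prof3 <- extract_indicators(med3, sets, period)
  expect_true(prof3$dementia)
  expect_equal(prof3$dementia_first_date, as.Date("2013-02-02"))

  expect_error(extract_indicators(med3, sets[-1], period), "dbs")
})

test_that("one claim may trigger several indicators independently", {
  overlap <- sets
  overlap$fall <- code_set("fall", data.frame(system = "DX", code = "SBOTH",
                                              match = "PREFIX"))
  overlap$dementia <- code_set("dementia",
                               data.frame(system = "DX", code = "SBOTH1",
                                          match = "EXACT"))
  prof <- extract_indicators(medical_claims_df("p1", "2013-06-01", "DX",
                                               "SBOTH1"),
                             overlap, period)
  expect_true(prof$fall)
  expect_true(prof$dementia)
})

test_that("indicators are monotone in evidence", {
  med <- medical_claims_df("p1", "2013-04-01", "DME", "SWALK1", "DME")
  more <- rbind(med, medical_claims_df("p1", "2013-05-01", "DX", "SDEM2"))
  before <- unlist(extract_indicators(med, sets, period)[names(sets)])
  after <- unlist(extract_indicators(more, sets, period)[names(sets)])
  expect_true(all(after >= before))
})

test_that("prevalence splits counts consistently across groups", {
  set.seed(23)
  n <- 400
  ids <- sprintf("q%03d", 1:n)
  apd <- rep(c(TRUE, FALSE), length.out = n)
  has_dem <- runif(n) < ifelse(apd, 0.3, 0.4)
  med <- medical_claims_df(ids[has_dem], "2013-03-03", "DX", "SDEM0")
  prof <- extract_indicators(med, sets, period, patient_ids = ids)
  cls <- data.frame(patient_id = ids, rule = "LED_GT_1000", is_apd = apd)

  prev <- indicator_prevalence(prof, cls)
  expect_equal(prev$n_overall, prev$n_mild_moderate + prev$n_apd)
  dem <- prev[prev$indicator == "dementia", ]
  expect_equal(dem$n_overall, sum(has_dem))
  expect_equal(dem$pct_apd, claims_pct(sum(has_dem & apd), sum(apd)))

  # everyone positive -> 100.0
  all_med <- medical_claims_df(ids, "2013-03-03", "DX", "SDEM0")
  prev_all <- indicator_prevalence(
    extract_indicators(all_med, sets, period, patient_ids = ids), cls)
  expect_equal(prev_all$pct_overall[prev_all$indicator == "dementia"], 100.0)

  # an empty severity group leaves percentages undefined
  cls_one <- transform(cls, is_apd = FALSE)
  expect_error(indicator_prevalence(prof, cls_one), "empty")
})
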