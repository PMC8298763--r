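test_that("pharmacy reader validates rows and reports rejections by line", {
  # header-only file
  empty <- write_tmp_csv(lines = paste(
    "patient_id,drug_id,fill_date,days_supply,quantity,strength_mg"))
  out <- read_pharmacy_claims(empty)
  expect_equal(nrow(out), 0)
  expect_equal(nrow(rejected_rows(out)), 0)

  # one valid row
  one <- write_tmp_csv(lines = c(
    "patient_id,drug_id,fill_date,days_supply,quantity,strength_mg",
    "p1,levodopa_ir,2013-01-01,30,90,100"))
  out <- read_pharmacy_claims(one)
  expect_equal(nrow(out), 1)
  expect_equal(out$days_supply, 30L)
  expect_s3_class(out$fill_date, "Date")

  # invalid days_supply: rejected, not dropped silently; line number kept
  bad <- write_tmp_csv(lines = c(
    "patient_id,drug_id,fill_date,days_supply,quantity,strength_mg",
    "p1,levodopa_ir,2013-01-01,0,90,100",
    "p1,levodopa_ir,2013-02-01,30,90,100",
    "p2,levodopa_ir,not-a-date,30,90,100"))
  expect_message(out <- read_pharmacy_claims(bad), "rejected 2")
  expect_equal(nrow(out), 1)
  rej <- rejected_rows(out)
  expect_equal(rej$line, c(2L, 4L))
  expect_match(rej$reason[1], "days_supply")
  expect_match(rej$reason[2], "fill_date")

  # missing required column is a schema error, not row errors
  noq <- write_tmp_csv(lines = c("patient_id,drug_id,fill_date",
                                 "p1,levodopa_ir,2013-01-01"))
  expect_error(read_pharmacy_claims(noq), "missing required column")
})

test_that("medical and beneficiary readers enforce their invariants", {
  med <- write_tmp_csv(lines = c(
    "patient_id,service_date,code_system,code,setting",
    "p1,2013-03-01,DX,V43.3,OUTPATIENT",
    "p1,2013-03-02,BOGUS,1234,OUTPATIENT",
    "p1,2013-03-03,DX,,OUTPATIENT"))
  expect_message(out <- read_medical_claims(med), "rejected 2")
  expect_equal(out$code, "V433")  # normalized on read

  ben <- write_tmp_csv(lines = c(
    paste("patient_id,birth_date,sex,race,region,enrollment,death_date,",
          "rx_risk_score", sep = ""),
    "p1,1940-05-01,F,WHITE,SOUTH,111111111111,,1.2",
    "p2,1940-05-01,M,WHITE,SOUTH,1111,,1.2",
    "p3,1940-05-01,M,WHITE,SOUTH,111111111111,1939-01-01,1.2",
    "p4,1940-05-01,M,,  ,111111111111,,"))
  expect_message(out <- read_beneficiaries(ben), "rejected 2")
  expect_equal(out$patient_id, c("p1", "p4"))
  expect_equal(out$race[2], "MISSING")   # missing values allowed, flagged
  rej <- rejected_rows(out)
  expect_match(rej$reason[1], "12 monthly")
  expect_match(rej$reason[2], "death_date precedes")
})

test_that("code normalization is idempotent and prefix matching works", {
  codes <- c("V43.3", "e885.0", " 332.0 ", "K000")
  expect_identical(normalize_code(normalize_code(codes)),
                   normalize_code(codes))
  cs <- code_set("x", data.frame(system = "DX", code = "332",
                                 match = "PREFIX"))
  expect_true(codes_match(cs, "DX", "3320"))
  expect_true(codes_match(cs, "DX", "332"))
  expect_false(codes_match(cs, "DX", "3330"))
  expect_false(codes_match(cs, "PROC", "3320"))  # system must match too

  # required setting filters
  cs2 <- code_set("w", data.frame(system = "DME", code = "SW1",
                                  match = "EXACT"),
                  required_setting = "DME")
  expect_true(codes_match(cs2, "DME", "SW1", "DME"))
  expect_false(codes_match(cs2, "DME", "SW1", "OUTPATIENT"))
})

test_that("code set construction and config reading catch bad input", {
  expect_error(code_set("x", data.frame(system = character(),
                                        code = character(),
                                        match = character())),
               "no entries")
  expect_error(code_set("x", data.frame(system = "ICD10", code = "A1",
                                        match = "EXACT")),
               "unknown code_system")

  # shipped default config defines exactly the nine indicators
  sets <- read_code_sets(system.file("extdata", "code_sets.yaml",
                                     package = "apdclaims"))
  expect_setequal(names(sets),
                  c("dbs", "fall", "hallucinations", "walker", "wheelchair",
                    "specialty_bed", "dementia", "snf", "hospice"))
  expect_equal(sets$walker$required_setting, "DME")

  # duplicate indicator block is an error
  dup <- tempfile(fileext = ".yaml")
  writeLines(c("dbs:", "  entries:",
               "    - {system: PROC, code: A1, match: EXACT}",
               "dbs:", "  entries:",
               "    - {system: PROC, code: A2, match: EXACT}"), dup)
  expect_error(read_code_sets(dup, require_nine = FALSE))

  # a non-nine config is rejected unless explicitly allowed
  one <- tempfile(fileext = ".yaml")
  writeLines(c("dbs:", "  entries:",
               "    - {system: PROC, code: A1, match: EXACT}"), one)
  expect_error(read_code_sets(one), "nine")
  expect_length(read_code_sets(one, require_nine = FALSE), 1)
})

test_that("results writer round-trips through the reader", {
  tab <- data.frame(rule = c("a", "b", "c"), or = c(1.5, 2.25, 0.8),
                    ci_low = c(1.1, 2.0, 0.5), p = c(0.01, 1e-8, 0.2))
  path <- tempfile(fileext = ".csv")
  write_results(tab, path)
  back <- as.data.frame(read_results(path))
  expect_equal(back, tab)

  # empty table -> header only
  write_results(tab[0, ], path)
  expect_equal(nrow(read_results(path)), 0)
  expect_equal(names(read_results(path)), names(tab))
  expect_error(write_results(NULL, path), "non-null")
})
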