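test_that("bundled registry loads all five models with published values", {
  reg <- load_model_registry()
  expect_named(reg, c("cambridge", "kuwaiti", "omani", "rotterdam",
                      "finnish"))
  expect_equal(reg$cambridge$intercept, -6.322)
  expect_equal(reg$omani$terms$age_40_59$coefficient, 1.800)
  expect_equal(reg$kuwaiti$terms$wc_gt100$coefficient, 1.930)
  expect_equal(reg$rotterdam$terms$age5_over55$coefficient, 0.190)
  # unobservable predictor carried as a fixed-zero term
  expect_true("high_glucose_history" %in% reg$finnish$fixed_zero_terms)
})

test_that("malformed registry entries are rejected with the offending term", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"broken": {"intercept": -1.0, "terms": [
    {"name": "x1", "derivation": {"type": "flag", "field": "fh_mother"}}
  ]}}', path)
  expect_error(load_model_registry(path), "x1")
  writeLines('{"broken": {"intercept": -1.0, "terms": [
    {"name": "x1", "coefficient": 0.5, "derivation": {"type": "wat"}}
  ]}}', path)
  expect_error(load_model_registry(path), "unknown derivation")
  writeLines("{not json", path)
  expect_error(load_model_registry(path), "parse")
})

test_that("registry serialization round-trips coefficients bit-for-bit", {
  reg <- load_model_registry()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_registry(reg, path)
  reg2 <- load_model_registry(path)
  for (nm in names(reg)) {
    expect_identical(reg2[[nm]]$intercept, reg[[nm]]$intercept)
    expect_identical(coef(reg2[[nm]]), coef(reg[[nm]]))
    expect_identical(reg2[[nm]]$fixed_zero_terms, reg[[nm]]$fixed_zero_terms)
  }
})

test_that("predictor encoding follows the sex-specific and band rules", {
  reg <- load_model_registry()
  # woman with WC 85 crosses the female cutoff of the Omani WC term
  x <- encode_predictors(make_record(sex = "female", waist = 85), reg$omani)
  expect_equal(unname(x[1, "wc_sex_high"]), 1)
  x <- encode_predictors(make_record(sex = "male", waist = 85), reg$omani)
  expect_equal(unname(x[1, "wc_sex_high"]), 0)
  # BMI below the lowest Cambridge band leaves all band indicators 0
  x <- encode_predictors(make_record(sex = "male", bmi = 24), reg$cambridge)
  expect_equal(unname(x[1, c("bmi_25_27", "bmi_27_30", "bmi_30")]),
               c(0, 0, 0))
  # Finnish age bands are mutually exclusive
  x <- encode_predictors(make_record(age = 57), reg$finnish)
  expect_equal(unname(x[1, c("age_45_54", "age_55_64")]), c(0, 1))
  # Rotterdam age term counts completed 5-year increments from 55, capped
  ages <- c(40, 54.9, 55, 59, 60, 74, 75, 80, 90)
  x <- encode_predictors(make_record(age = ages, id = seq_along(ages)),
                         reg$rotterdam)
  expect_equal(unname(x[, "age5_over55"]), c(0, 0, 1, 1, 2, 4, 5, 5, 5))
  # Kuwaiti WC term is strictly greater than 100
  x <- encode_predictors(make_record(waist = c(100, 100.1)), reg$kuwaiti)
  expect_equal(unname(x[, "wc_gt100"]), c(0, 1))
  # Omani blood-pressure term fires on either threshold
  x <- encode_predictors(
    make_record(sbp = c(141, 120, 120), dbp = c(70, 91, 89)), reg$omani)
  expect_equal(unname(x[, "bp_high"]), c(1, 1, 0))
})

test_that("missing raw fields are refused by name", {
  reg <- load_model_registry()
  rec <- make_record()
  rec$bmi <- NA_real_
  expect_error(encode_predictors(rec, reg$cambridge), "bmi")
})

test_that("linear predictor and risk match hand-computed examples", {
  reg <- load_model_registry()
  # all-zero feature vector returns the intercept
  zero <- make_record(sex = "male", age = 0, bmi = 20, waist = 60,
                      sbp = 100, dbp = 60)
  expect_equal(predict(reg$cambridge, zero, type = "link"), -6.322)
  # male, age 50, BMI 26, never-smoker, no meds, no family history
  lp <- predict(reg$cambridge, make_record(sex = "male"), type = "link")
  expect_equal(lp, -6.322 + 0.063 * 50 + 0.699, tolerance = 1e-12)
  # Kuwaiti: age 50, WC 105, no sibling history, no antihypertensives
  lp <- predict(reg$kuwaiti, make_record(waist = 105), type = "link")
  expect_equal(lp, -5.018 + 1.315 + 1.930, tolerance = 1e-12)
  expect_equal(round(predict_risk(lp), 3), 0.145)
  expect_equal(predict_risk(0), 0.5)
  expect_equal(predict_risk(-700), 0)
  expect_error(predict_risk(Inf), "finite")
})

test_that("band indicators are exclusive and risks stay in (0,1) cohort-wide", {
  reg <- load_model_registry()
  co <- make_cohort(n = 300, seed = 11)
  for (nm in names(reg)) {
    m <- reg[[nm]]
    x <- encode_predictors(co, m)
    bands <- split(names(m$terms),
                   vapply(m$terms, function(tm) tm$band %||% "", ""))
    for (fam in setdiff(names(bands), "")) {
      expect_true(all(rowSums(x[, bands[[fam]], drop = FALSE]) <= 1),
                  label = sprintf("%s band family '%s' exclusive", nm, fam))
    }
    p <- predict(m, co)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("risk is monotone in positive-coefficient terms", {
  reg <- load_model_registry()
  lo <- predict(reg$kuwaiti, make_record(waist = 90))
  hi <- predict(reg$kuwaiti, make_record(waist = 110))
  expect_gt(hi, lo)
  base <- predict(reg$omani, make_record(fh_mother = 0, fh_sister = 0))
  fh <- predict(reg$omani, make_record(fh_mother = 1, fh_sister = 0))
  expect_gt(fh, base)
})
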