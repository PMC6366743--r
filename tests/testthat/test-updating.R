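reg <- load_model_registry()

test_that("intercept adjustment recovers the closed-form logit correction", {
  # a model predicting constant risk plogis(-1) on data with prevalence 1/2
  const <- risk_model("const", -1, terms = list())
  dat <- data.frame(outcome = rep(c(0L, 1L), 25))
  up <- method1_intercept_adjustment(const, dat)
  expect_equal(up$correction_factor, 1, tolerance = 1e-12)
  expect_equal(up$final_model$intercept, 0, tolerance = 1e-12)

  # mean predicted risk already equal to prevalence: nothing changes
  half <- risk_model("half", 0, terms = list())
  up0 <- method1_intercept_adjustment(half, dat)
  expect_equal(up0$correction_factor, 0, tolerance = 1e-12)

  expect_error(method1_intercept_adjustment(const,
               data.frame(outcome = rep(1L, 10))), "prevalence")
})

test_that("intercept adjustment never changes discrimination", {
  co <- exclude_diagnosed(make_cohort(n = 600, seed = 12, flagged = 60))
  up <- method1_intercept_adjustment(reg$cambridge, co)
  c0 <- c_statistic(predict(reg$cambridge, co), co$outcome)$estimate
  c1 <- c_statistic(predict(up$final_model, co), co$outcome)$estimate
  expect_equal(c1, c0, tolerance = 1e-15)
})

test_that("logistic calibration is self-consistent under the true model", {
  # data simulated from the model itself: slope near 1, intercept near 0
  truth <- reg$omani
  co <- make_cohort(n = 5000, seed = 13, true_model = truth,
                    missingness = FALSE)
  truth_cal <- attr(co, "true_model")
  up <- method2_logistic_calibration(truth_cal, co)
  expect_lt(abs(up$calibration_slope - 1), 0.15)
  expect_lt(abs(up$calibration_intercept), 0.5)

  # the composed final model reproduces a + b * LP exactly
  lp <- predict(truth_cal, co, type = "link")
  lp2 <- predict(up$final_model, co, type = "link")
  expect_equal(lp2, up$calibration_intercept + up$calibration_slope * lp,
               tolerance = 1e-12)

  # outcome shuffled independently of the linear predictor: slope near 0
  shuffled <- co
  set.seed(14)
  shuffled$outcome <- sample(shuffled$outcome)
  up0 <- method2_logistic_calibration(truth_cal, shuffled)
  expect_lt(abs(up0$calibration_slope), 0.15)

  # training E/O is exactly 1 at the ML solution
  p <- predict(up$final_model, co)
  expect_equal(eo_ratio(p, co$outcome), 1, tolerance = 1e-6)

  const <- risk_model("const", -1, terms = list())
  expect_error(method2_logistic_calibration(const, co), "constant")
})

test_that("likelihood-ratio test matches the chi-square reference", {
  expect_equal(lr_test(-10, -10, 1)$p_value, 1)
  expect_equal(lr_test(-12, -12 + 3.841 / 2, 1)$p_value, 0.05,
               tolerance = 1e-3)
  expect_equal(lr_test(-5, -5, 3)$p_value, 1)
  expect_error(lr_test(-5, -4, 0), "df")
  expect_warning(lr_test(-4, -5, 1), "below null")
})

test_that("revision collapses to logistic calibration when nothing selected", {
  co <- make_cohort(n = 900, seed = 15, flagged = 90, missingness = FALSE)
  an <- exclude_diagnosed(co)
  truth <- attr(co, "true_model")   # data generated exactly from this model
  m3 <- method3_revision(truth, an, alpha = 1e-9)  # effectively never select
  m2 <- method2_logistic_calibration(truth, an)
  expect_equal(m3$calibration_slope, m2$calibration_slope, tolerance = 1e-9)
  expect_equal(m3$calibration_intercept, m2$calibration_intercept,
               tolerance = 1e-9)
  expect_length(m3$deviations, 0)
  expect_equal(predict(m3$final_model, an), predict(m2$final_model, an),
               tolerance = 1e-9)
})

test_that("revision detects a genuinely shifted coefficient", {
  base <- reg$cambridge
  truth <- base
  truth$terms$fh_parent_and_sibling$coefficient <-
    2 * base$terms$fh_parent_and_sibling$coefficient
  co <- make_cohort(n = 5000, seed = 16, true_model = truth,
                    calibrate = FALSE, missingness = FALSE)
  m3 <- method3_revision(base, co, shrink = FALSE)
  row <- m3$screening[m3$screening$term == "fh_parent_and_sibling", ]
  expect_true(row$selected)
  expect_gt(m3$deviations[["fh_parent_and_sibling"]], 0)
  # composed model equals alpha + beta*LP + sum(gamma_j x_j) on every record
  lp <- predict(base, co, type = "link")
  x <- encode_predictors(co, base)
  manual <- m3$calibration_intercept + m3$calibration_slope * lp +
    drop(x[, names(m3$deviations), drop = FALSE] %*% m3$deviations)
  expect_equal(predict(m3$final_model, co, type = "link"), manual,
               tolerance = 1e-12)
})

test_that("re-estimation matches a generic optimizer on a tiny dataset", {
  toy <- toy_logistic_data()
  model <- risk_model("toy", 0, terms = list(
    list(name = "x1", coefficient = 0,
         derivation = list(type = "flag", field = "x1")),
    list(name = "x2", coefficient = 0,
         derivation = list(type = "continuous", field = "x2")),
    list(name = "x3", coefficient = 0,
         derivation = list(type = "flag", field = "x3"))))
  dat <- cbind(as.data.frame(toy$x), outcome = toy$y)
  m4 <- method4_reestimation(model, dat, shrink = FALSE)
  opt <- optim(rep(0, 4), toy_negll, gr = toy_negll_grad,
               x = toy$x, y = toy$y, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  expect_equal(unname(m4$ml_coefficients), opt$par, tolerance = 1e-6)
})

test_that("re-estimation recovers generating coefficients at large n", {
  truth <- reg$kuwaiti
  co <- make_cohort(n = 10000, seed = 17, true_model = truth,
                    calibrate = FALSE, missingness = FALSE)
  m4 <- method4_reestimation(truth, co, shrink = FALSE)
  tv <- c(truth$intercept, coef(truth))
  covered <- abs(m4$ml_coefficients - tv) <= 1.96 * m4$se
  expect_gte(mean(covered), 0.8)
  expect_lt(max(abs(m4$ml_coefficients - tv)), 0.5)
})

test_that("perfect association triggers a separation error", {
  dat <- data.frame(fh_mother = rep(c(0, 1), each = 10),
                    fh_father = 0, fh_sister = 0, fh_brother = 0,
                    outcome = rep(c(0L, 1L), each = 10))
  model <- risk_model("sep", 0, terms = list(
    list(name = "fh", coefficient = 1,
         derivation = list(type = "family_history", rule = "parent"))))
  expect_error(method4_reestimation(model, dat, shrink = FALSE),
               "separation")
})

test_that("training log-likelihoods are ordered across nested methods", {
  loglik <- function(p, y) sum(dbinom(y, 1, p, log = TRUE))
  for (s in 1:3) {
    co <- exclude_diagnosed(make_cohort(n = 800, seed = 700 + s,
                                        flagged = 80, missingness = FALSE))
    y <- co$outcome
    base <- reg$omani
    ll0 <- loglik(predict(base, co), y)
    ll1 <- loglik(predict(method1_intercept_adjustment(base, co)$final_model,
                          co), y)
    ll2 <- loglik(predict(method2_logistic_calibration(base, co)$final_model,
                          co), y)
    m3 <- method3_revision(base, co, shrink = FALSE)
    ll3 <- loglik(predict(m3$final_model, co), y)
    ll4 <- method4_reestimation(base, co, shrink = FALSE)$loglik
    expect_true(ll0 <= ll1 + 1e-9)
    expect_true(ll1 <= ll2 + 1e-9)
    expect_true(ll2 <= ll3 + 1e-9)
    expect_true(ll2 <= ll4 + 1e-9)
  }
})

test_that("extension screens, selects and composes new predictors", {
  # truth: Cambridge recalibrated + a strong waist effect absent from it
  co0 <- make_cohort(n = 4000, seed = 18, missingness = FALSE)
  base <- reg$cambridge
  a <- calibrate_true_intercept(base, co0, 0.15)
  truth <- base
  truth$intercept <- a
  truth$terms$wc_extra <- list(
    name = "wc_extra", coefficient = 1.2,
    derivation = list(type = "waist_sex_cutoff", male = 94, female = 80))
  co <- make_cohort(n = 4000, seed = 18, true_model = truth,
                    calibrate = FALSE, missingness = FALSE)
  sp <- split_cohort(co, seed = 19)
  m5 <- method5_extension(base, sp$train, shrink = FALSE)
  expect_true("wc_sex_high" %in% names(m5$added_terms))
  expect_gt(m5$added_terms[["wc_sex_high"]], 0)
  # held-out discrimination beats plain recalibration
  m2 <- method2_logistic_calibration(base, sp$train)
  c5 <- c_statistic(predict(m5$final_model, sp$test), sp$test$outcome)$estimate
  c2 <- c_statistic(predict(m2$final_model, sp$test), sp$test$outcome)$estimate
  expect_gt(c5, c2)

  # empty candidate list reduces to Method 2
  m5e <- method5_extension(base, sp$train, candidates = list())
  expect_equal(m5e$calibration_slope, m2$calibration_slope, tolerance = 1e-9)
  expect_length(m5e$added_terms, 0)

  # candidates already in the model are refused
  expect_error(
    method5_extension(base, sp$train,
                      candidates = candidate_pool()["antihypertensive"]),
    "already in model")
})

test_that("backward stepwise development recovers a sparse truth", {
  # truth uses exactly three strong predictors from the candidate pool
  truth <- risk_model("sparse", -3, terms = list(
    list(name = "age", coefficient = 0.05,
         derivation = list(type = "continuous", field = "age")),
    list(name = "wc_sex_high", coefficient = 1.4,
         derivation = list(type = "waist_sex_cutoff", male = 94, female = 80)),
    list(name = "antihypertensive", coefficient = 1.0,
         derivation = list(type = "flag", field = "antihypertensive"))))
  co <- make_cohort(n = 5000, seed = 20, true_model = truth,
                    calibrate = TRUE, target = 0.2, missingness = FALSE)
  dev <- develop_model(co, alpha = 0.05, shrink = FALSE)
  expect_true(all(c("age", "wc_sex_high", "antihypertensive")
                  %in% dev$retained))

  # alpha = 1 keeps the full candidate set
  sm <- make_cohort(n = 1200, seed = 21, missingness = FALSE)
  dev_full <- develop_model(sm, alpha = 1, shrink = FALSE)
  expect_setequal(dev_full$retained, names(development_candidates()))

  # outcome independent of all candidates: intercept-only, with warning
  null <- sm
  set.seed(22)
  null$outcome <- rbinom(nrow(null), 1, 0.15)
  suppressWarnings({
    dev0 <- develop_model(null, alpha = 0.001, shrink = FALSE)
  })
  expect_lte(length(dev0$retained), 1)
})
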