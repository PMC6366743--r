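test_that("C-statistic matches hand examples and handles ties", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2),
                           c(1, 1, 0, 0))$estimate, 1)
  expect_equal(c_statistic(rep(0.3, 10), rep(c(0, 1), 5))$estimate, 0.5)
  expect_equal(c_statistic(c(0.2, 0.6, 0.4, 0.8),
                           c(0, 0, 1, 1))$estimate, 0.75)
  expect_error(c_statistic(c(0.1, 0.2), c(1, 1)), "both")
})

test_that("C-statistic agrees with brute-force pair enumeration", {
  set.seed(40)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)  # force some ties
    expect_equal(c_statistic(p, y)$estimate, brute_force_cstat(p, y),
                 tolerance = 1e-12)
  }
})

test_that("DeLong interval agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(41)
  y <- rbinom(300, 1, 0.25)
  p <- plogis(-1 + 2 * y + rnorm(300))
  ours <- c_statistic(p, y)
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, p), method = "delong"))
  expect_equal(ours$estimate, as.numeric(ref[2]), tolerance = 1e-9)
  expect_equal(ours$ci[1], as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(ours$ci[2], as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("E/O ratio is the expected-over-observed event total", {
  expect_equal(eo_ratio(c(0.1, 0.2, 0.3), c(0, 0, 1)), 0.6)
  probs <- rep(81 / 1083, 1083)
  outcomes <- c(rep(1, 162), rep(0, 1083 - 162))
  expect_equal(eo_ratio(probs, outcomes), 0.5, tolerance = 1e-12)
  expect_error(eo_ratio(c(0.2, 0.3), c(0, 0)), "events")
})

test_that("Poisson E/O interval follows the log-scale closed form", {
  ci <- eo_confidence_interval(0.48, 162)
  expect_equal(ci, 0.48 * exp(c(-1, 1) * qnorm(0.975) / sqrt(162)),
               tolerance = 1e-12)
  # interval collapses onto the ratio as O grows
  wide <- eo_confidence_interval(1.2, 50)
  narrow <- eo_confidence_interval(1.2, 5e6)
  expect_lt(diff(narrow), 0.01)
  expect_gt(diff(wide), diff(narrow))
  # exact chi-square bounds are close but wider for small O
  ex <- eo_confidence_interval(1.2, 20, exact = TRUE)
  ap <- eo_confidence_interval(1.2, 20)
  expect_equal(ex, ap, tolerance = 0.1)
  expect_error(eo_confidence_interval(1.2, 0), "at least 1")
})

test_that("Brier score and Yates slope match hand arithmetic", {
  expect_equal(brier_score(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brier_score(rep(0.5, 8), rbinom(8, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.8, 0.4), c(1, 0)), 0.10)
  expect_equal(yates_slope(c(0.6, 0.6, 0.2, 0.2), c(1, 1, 0, 0)), 0.4)
  expect_equal(yates_slope(c(0.3, 0.3, 0.3, 0.3), c(1, 0, 1, 0)), 0)
  expect_equal(yates_slope(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_error(yates_slope(c(0.2, 0.3), c(1, 1)), "both")
})

test_that("affine rank-preserving transforms move Brier but never C", {
  set.seed(42)
  y <- rbinom(400, 1, 0.2)
  p <- plogis(-1.5 + 1.5 * y + rnorm(400))
  p2 <- plogis(0.5 + 2 * qlogis(p))
  expect_equal(c_statistic(p2, y)$estimate, c_statistic(p, y)$estimate,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(brier_score(p2, y), brier_score(p, y))))
})

test_that("calibration curves bin by risk deciles and merge degenerate bins", {
  set.seed(43)
  p <- runif(2000)
  y <- rbinom(2000, 1, p)  # perfectly calibrated by construction
  cc <- calibration_curve(p, y)
  expect_equal(sum(cc$n), 2000)
  expect_equal(nrow(cc), 10)
  # every decile close to the identity line (binomial noise ~3 SE)
  expect_true(all(abs(cc$observed_proportion - cc$mean_predicted) <
                    3 * sqrt(0.25 / cc$n) + 1e-9))
  expect_true(all(cc$mean_predicted >= 0 & cc$mean_predicted <= 1))

  expect_warning(one <- calibration_curve(rep(0.3, 100), rbinom(100, 1, 0.3)),
                 "merged")
  expect_equal(nrow(one), 1)
  expect_error(calibration_curve(c(0.1, 0.2), c(0, 1), n_bins = 10), "bin")
})

test_that("the combined report is internally consistent", {
  set.seed(44)
  y <- rbinom(500, 1, 0.25)
  p <- plogis(-1 + 1.2 * y + rnorm(500))
  r <- performance_report(p, y)
  expect_equal(r$expected_events, sum(p))
  expect_equal(r$events, sum(y))
  expect_equal(r$eo_ratio, sum(p) / sum(y))
  expect_true(r$eo_ci[1] < r$eo_ratio && r$eo_ratio < r$eo_ci[2])
  expect_true(r$c_ci[1] <= r$c_statistic && r$c_statistic <= r$c_ci[2])
})
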