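#' Configuration for the synthetic screening cohort generator
#'
#' Defaults emulate the marginal structure of a South African community
#' diabetes-screening sample: 1256 recruited participants of whom 173 carry
#' a previous diabetes diagnosis, age 51.9 (SD 14.9) years, 23.2% male, BMI
#' 29.7 (7.0) kg/m2, waist circumference 95.8 (15.3) cm, SBP/DBP 124.3
#' (20.0) / 76.0 (12.7) mmHg, the printed medication / family-history /
#' lifestyle prevalences, roughly 15% undiagnosed diabetes among
#' participants without a prior diagnosis, and heavy missingness in the
#' family-history block (about 25% per relative).
#'
#' @param n_recruited Number of participants recruited.
#' @param n_previously_diagnosed Number flagged as previously diagnosed
#'   (excluded from the analysis set and never given a simulated screening
#'   outcome).
#' @param continuous_marginals Named list `field -> c(mean, sd)` for age,
#'   bmi, waist, sbp, dbp.
#' @param binary_prevalences Named vector of probabilities for `male` and
#'   the 0/1 flags.
#' @param smoking_probs,drinking_probs Named probability vectors over
#'   `never`/`ex`/`current` (must sum to 1).
#' @param education_probs Named probability vector over
#'   `primary`/`high_school`/`university`.
#' @param missingness_rates Named vector of per-field MCAR masking rates,
#'   applied by [inject_missingness()].
#' @param correlations `c(waist_bmi = , sbp_dbp = )` pairwise latent
#'   (Gaussian copula) correlations; all other pairs independent.
#' @param bounds Named list of physiologic truncation ranges for the
#'   continuous fields.
#' @param true_model `risk_model` generating the outcome; `NULL` means the
#'   bundled Omani model.
#' @param calibrate_intercept If `TRUE` the true model's intercept is
#'   re-solved on each generated cohort so that mean predicted risk among
#'   non-excluded records equals `target_prevalence`.
#' @param target_prevalence Expected undiagnosed-diabetes prevalence among
#'   non-excluded records.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_recruited = 1256,
    n_previously_diagnosed = 173,
    continuous_marginals = list(
      age = c(51.9, 14.9), bmi = c(29.7, 7.0), waist = c(95.8, 15.3),
      sbp = c(124.3, 20.0), dbp = c(76.0, 12.7)),
    binary_prevalences = c(
      male = 0.232, antihypertensive = 0.345, lipid_lowering = 0.037,
      corticosteroids = 0.011, fh_mother = 0.115, fh_father = 0.056,
      fh_sister = 0.095, fh_brother = 0.062),
    smoking_probs = c(never = 0.45, ex = 0.15, current = 0.40),
    drinking_probs = c(never = 0.599, ex = 0.15, current = 0.251),
    education_probs = c(primary = 0.779, high_school = 0.121,
                        university = 0.10),
    missingness_rates = c(
      fh_mother = 0.251, fh_father = 0.249, fh_sister = 0.250,
      fh_brother = 0.251, smoking = 0.061, bmi = 0.03, waist = 0.03,
      sbp = 0.03, dbp = 0.03, antihypertensive = 0.03,
      lipid_lowering = 0.03, corticosteroids = 0.03, drinking = 0.03,
      education = 0.03),
    correlations = c(waist_bmi = 0.8, sbp_dbp = 0.6),
    bounds = list(age = c(20, 90), bmi = c(14, 60), waist = c(50, 160),
                  sbp = c(80, 220), dbp = c(40, 130)),
    true_model = NULL,
    calibrate_intercept = TRUE,
    target_prevalence = 0.15,
    seed = 1L) {
  cfg <- list(n_recruited = n_recruited,
              n_previously_diagnosed = n_previously_diagnosed,
              continuous_marginals = continuous_marginals,
              binary_prevalences = binary_prevalences,
              smoking_probs = smoking_probs,
              drinking_probs = drinking_probs,
              education_probs = education_probs,
              missingness_rates = missingness_rates,
              correlations = correlations,
              bounds = bounds,
              true_model = true_model,
              calibrate_intercept = calibrate_intercept,
              target_prevalence = target_prevalence,
              seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_previously_diagnosed >= cfg$n_recruited)
    stop("n_previously_diagnosed must be smaller than n_recruited")
  props <- c(cfg$binary_prevalences, cfg$smoking_probs, cfg$drinking_probs,
             cfg$education_probs, cfg$missingness_rates)
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  for (p in list(cfg$smoking_probs, cfg$drinking_probs, cfg$education_probs))
    if (abs(sum(p) - 1) > 1e-8) stop("category probabilities must sum to 1")
  sds <- vapply(cfg$continuous_marginals, `[`, numeric(1), 2)
  if (any(sds <= 0)) stop("marginal standard deviations must be positive")
  if (cfg$target_prevalence <= 0 || cfg$target_prevalence >= 1)
    stop("target_prevalence must lie strictly inside (0, 1)")
  invisible(cfg)
}

## Truncated-normal quantile transform of copula uniforms.
qtnorm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Generate a synthetic screening cohort
#'
#' Draws the continuous fields from truncated-normal marginals coupled
#' through a Gaussian copula (waist~BMI and SBP~DBP correlated, other pairs
#' independent), the categorical fields from their configured prevalences,
#' flags `n_previously_diagnosed` randomly chosen records as previously
#' diagnosed, and simulates the undiagnosed-diabetes outcome for the
#' remaining records as Bernoulli draws from the true model's predicted
#' risk. With `calibrate_intercept = TRUE` the true model's intercept is
#' first solved so mean predicted risk among non-excluded records equals
#' `target_prevalence` (see [calibrate_true_intercept()]). Missingness is
#' then injected at the configured MCAR rates.
#'
#' @param config A [cohort_config()].
#' @param with_missingness Set `FALSE` to keep the cohort fully observed.
#' @return Data frame, one row per participant: `id`, `sex`, `age`, `bmi`,
#'   `waist`, `sbp`, `dbp`, 0/1 flags (`antihypertensive`,
#'   `lipid_lowering`, `corticosteroids`, `fh_mother`, `fh_father`,
#'   `fh_sister`, `fh_brother`), `smoking`, `drinking`, `education`,
#'   `previously_diagnosed` and `outcome` (`NA` for previously diagnosed
#'   records, who do not undergo the screening test). The calibrated true
#'   model is attached as attribute `"true_model"`.
#' @export
generate_cohort <- function(config = cohort_config(), with_missingness = TRUE) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_recruited
  fields <- names(config$continuous_marginals)

  ## Gaussian copula over the continuous block
  k <- length(fields)
  rho <- diag(k)
  dimnames(rho) <- list(fields, fields)
  pair <- function(a, b, r) {
    if (all(c(a, b) %in% fields)) rho[a, b] <<- rho[b, a] <<- r
  }
  pair("waist", "bmi", unname(config$correlations["waist_bmi"]))
  pair("sbp", "dbp", unname(config$correlations["sbp_dbp"]))
  z <- matrix(stats::rnorm(n * k), n, k) %*% chol(rho)
  u <- stats::pnorm(z)
  cont <- lapply(seq_along(fields), function(j) {
    f <- fields[j]
    m <- config$continuous_marginals[[f]]
    b <- config$bounds[[f]] %||% c(-Inf, Inf)
    qtnorm(u[, j], m[1], m[2], b[1], b[2])
  })
  names(cont) <- fields

  draw_cat <- function(probs) {
    sample(names(probs), n, replace = TRUE, prob = probs)
  }
  bp <- config$binary_prevalences
  cohort <- data.frame(
    id = seq_len(n),
    sex = ifelse(stats::rbinom(n, 1, bp[["male"]]) == 1, "male", "female"),
    age = cont$age, bmi = cont$bmi, waist = cont$waist,
    sbp = cont$sbp, dbp = cont$dbp,
    antihypertensive = stats::rbinom(n, 1, bp[["antihypertensive"]]),
    lipid_lowering = stats::rbinom(n, 1, bp[["lipid_lowering"]]),
    corticosteroids = stats::rbinom(n, 1, bp[["corticosteroids"]]),
    fh_mother = stats::rbinom(n, 1, bp[["fh_mother"]]),
    fh_father = stats::rbinom(n, 1, bp[["fh_father"]]),
    fh_sister = stats::rbinom(n, 1, bp[["fh_sister"]]),
    fh_brother = stats::rbinom(n, 1, bp[["fh_brother"]]),
    smoking = draw_cat(config$smoking_probs),
    drinking = draw_cat(config$drinking_probs),
    education = draw_cat(config$education_probs),
    stringsAsFactors = FALSE)

  cohort$previously_diagnosed <- 0L
  cohort$previously_diagnosed[
    sample.int(n, config$n_previously_diagnosed)] <- 1L

  true_model <- config$true_model %||% load_model_registry()$omani
  eligible <- cohort[cohort$previously_diagnosed == 0L, ]
  if (isTRUE(config$calibrate_intercept)) {
    true_model$intercept <- calibrate_true_intercept(
      true_model, eligible, config$target_prevalence)
  }
  p <- predict(true_model, cohort)
  cohort$outcome <- stats::rbinom(n, 1, p)
  cohort$outcome[cohort$previously_diagnosed == 1L] <- NA_integer_

  if (with_missingness && length(config$missingness_rates))
    cohort <- inject_missingness(cohort, config$missingness_rates)
  attr(cohort, "true_model") <- true_model
  cohort
}

#' Mask cohort fields completely at random
#'
#' Each listed field is independently set to `NA` with its configured rate
#' (MCAR). `id`, `previously_diagnosed` and `outcome` may never be masked.
#'
#' @param cohort Cohort data frame.
#' @param rates Named vector of masking probabilities in `[0, 1]`.
#' @param seed Optional seed; by default masking continues the caller's RNG
#'   stream (as inside [generate_cohort()]).
#' @return The cohort with missing markers injected.
#' @export
inject_missingness <- function(cohort, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  protected <- c("id", "previously_diagnosed", "outcome")
  unknown <- setdiff(names(rates), names(cohort))
  if (length(unknown))
    stop(sprintf("missingness rate given for nonexistent field(s): %s",
                 paste(unknown, collapse = ", ")))
  if (any(names(rates) %in% protected))
    stop("id, previously_diagnosed and outcome may not be masked")
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  n <- nrow(cohort)
  for (f in names(rates)) {
    mask <- stats::runif(n) < rates[[f]]
    cohort[[f]][mask] <- NA
  }
  cohort
}

#' Solve the outcome-model intercept for a target prevalence
#'
#' Monotone root-finding on the intercept of `model` so that the mean
#' predicted risk over `cohort` equals `target_prevalence` (within 1e-6;
#' internal root tolerance much tighter). Used by the generator so any
#' registry model can serve as the data-generating truth at a chosen
#' prevalence.
#'
#' @param model A [risk_model()].
#' @param cohort Non-empty covariate sample (records; outcome not needed).
#' @param target_prevalence Target mean risk, strictly inside (0, 1).
#' @return Calibrated intercept value.
#' @export
calibrate_true_intercept <- function(model, cohort, target_prevalence) {
  if (nrow(cohort) == 0) stop("covariate sample is empty")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie strictly inside (0, 1)")
  x <- encode_predictors(cohort, model)
  lp0 <- drop(x[, names(coef(model)), drop = FALSE] %*% coef(model))
  f <- function(a) mean(stats::plogis(a + lp0)) - target_prevalence
  root <- tryCatch(
    stats::uniroot(f, lower = -40, upper = 40, tol = 1e-10),
    error = function(e) stop(sprintf(
      "intercept calibration failed: %s", conditionMessage(e)), call. = FALSE))
  a <- root$root
  if (abs(f(a)) > 1e-6)
    stop("intercept calibration did not reach the target prevalence")
  a
}

#' Write / read a cohort as CSV (empty cell = missing)
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `path` (write) or the cohort (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}
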