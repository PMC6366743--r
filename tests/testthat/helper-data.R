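# Shared fixtures, all built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

# One (or more, via vector arguments) fully observed participant records;
# override fields via ...
make_record <- function(...) {
  rec <- list(
    id = 1L, sex = "female", age = 50, bmi = 26, waist = 90, sbp = 120,
    dbp = 70, antihypertensive = 0, lipid_lowering = 0, corticosteroids = 0,
    fh_mother = 0, fh_father = 0, fh_sister = 0, fh_brother = 0,
    smoking = "never", drinking = "never", education = "primary",
    previously_diagnosed = 0L, outcome = 0L)
  args <- list(...)
  for (nm in names(args)) rec[[nm]] <- args[[nm]]
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# Small fully observed synthetic cohort
make_cohort <- function(n = 400, seed = 1, flagged = 0, true_model = NULL,
                        calibrate = TRUE, target = 0.15,
                        missingness = FALSE) {
  cfg <- cohort_config(n_recruited = n, n_previously_diagnosed = flagged,
                       true_model = true_model,
                       calibrate_intercept = calibrate,
                       target_prevalence = target, seed = seed)
  generate_cohort(cfg, with_missingness = missingness)
}

# Independent O(n^2) pair-count oracle for the concordance statistic
brute_force_cstat <- function(probs, outcomes) {
  ev <- probs[outcomes == 1]
  ne <- probs[outcomes == 0]
  tot <- 0
  for (a in ev) for (b in ne)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ev) * length(ne))
}

# Tiny deterministic logistic dataset for ML oracle checks
toy_logistic_data <- function() {
  x <- cbind(x1 = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
             x2 = c(-1.2, 0.4, 0.8, -0.5, 1.5, 0.2, -0.9, 1.1,
                    0.3, -1.4, 0.6, 0.1),
             x3 = c(0, 0, 1, 1, 0, 0, 1, 1, 0, 1, 0, 1))
  y <- c(0, 1, 0, 1, 1, 0, 0, 1, 0, 0, 1, 1)
  list(x = x, y = y)
}

# Negative log-likelihood and gradient for the generic-optimizer oracle
toy_negll <- function(beta, x, y) {
  lp <- beta[1] + drop(x %*% beta[-1])
  -sum(y * lp - log1p(exp(lp)))
}
toy_negll_grad <- function(beta, x, y) {
  lp <- beta[1] + drop(x %*% beta[-1])
  r <- plogis(lp) - y
  c(sum(r), drop(crossprod(x, r)))
}
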