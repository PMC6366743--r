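## ---- update results ---------------------------------------------------

new_update_result <- function(method, base_model, final_model, ...,
                              internal = NULL) {
  structure(c(list(method = method, base_model = base_model,
                   final_model = final_model), list(...),
              list(internal = internal)),
            class = "update_result")
}

#' @export
print.update_result <- function(x, ...) {
  cat(sprintf("<update_result> method %s on model '%s'\n",
              x$method, x$base_model$name %||% "<none>"))
  if (!is.null(x$correction_factor))
    cat(sprintf("  correction factor:    %8.4f\n", x$correction_factor))
  if (!is.null(x$calibration_intercept))
    cat(sprintf("  calibration intercept:%8.4f\n", x$calibration_intercept))
  if (!is.null(x$calibration_slope))
    cat(sprintf("  calibration slope:    %8.4f\n", x$calibration_slope))
  if (length(x$deviations)) {
    cat("  deviations:\n")
    for (nm in names(x$deviations))
      cat(sprintf("    %-22s %8.4f\n", nm, x$deviations[[nm]]))
  }
  if (length(x$added_terms)) {
    cat("  added terms:\n")
    for (nm in names(x$added_terms))
      cat(sprintf("    %-22s %8.4f\n", nm, x$added_terms[[nm]]))
  }
  if (length(x$shrinkage_factors))
    cat(sprintf("  shrinkage factors: mean %.3f (B-bootstrap)\n",
                mean(x$shrinkage_factors)))
  invisible(x)
}

get_outcome <- function(data) {
  y <- data$outcome
  if (is.null(y)) stop("data must carry an 'outcome' column")
  if (anyNA(y)) stop("outcome contains missing values; exclude or impute first")
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")
  as.numeric(y)
}

## intercept a + slope b applied to a whole model: LP' = a + b * LP
rescale_model <- function(model, a, b, suffix) {
  out <- model
  out$name <- paste0(model$name, suffix)
  out$intercept <- a + b * model$intercept
  for (nm in names(out$terms))
    out$terms[[nm]]$coefficient <- b * out$terms[[nm]]$coefficient
  out
}

## ---- method 1: intercept adjustment ------------------------------------

#' Method 1: intercept adjustment
#'
#' Shifts the model intercept by the correction factor
#' `logit(observed prevalence) - logit(mean predicted risk)`, matching the
#' model's average prediction to the disease prevalence of the new
#' population. A pure shift of the linear predictor, so discrimination is
#' untouched.
#'
#' @param model A [risk_model()].
#' @param data Imputed cohort with a 0/1 `outcome`.
#' @return An `update_result` with `correction_factor` and `final_model`.
#' @export
method1_intercept_adjustment <- function(model, data) {
  y <- get_outcome(data)
  prev <- mean(y)
  if (prev <= 0 || prev >= 1)
    stop("observed prevalence is 0 or 1; logit correction undefined")
  p <- predict(model, data)
  cf <- logit(prev) - logit(mean(p))
  final <- model
  final$name <- paste0(model$name, "_m1")
  final$intercept <- model$intercept + cf
  new_update_result("1", model, final, correction_factor = cf)
}

## ---- method 2: logistic calibration ------------------------------------

#' Method 2: logistic calibration
#'
#' Maximum-likelihood fit of `outcome ~ a + b * LP` where LP is the
#' original model's linear predictor. The calibration intercept `a` fixes
#' calibration-in-the-large and the slope `b` (typically < 1 in a new
#' population) uniformly rescales the published coefficients. The final
#' model has intercept `a + b * intercept` and every coefficient multiplied
#' by `b`, so its linear predictor equals `a + b * LP` exactly.
#'
#' @inheritParams method1_intercept_adjustment
#' @return An `update_result` with `calibration_intercept`,
#'   `calibration_slope` and `final_model`.
#' @export
method2_logistic_calibration <- function(model, data) {
  y <- get_outcome(data)
  lp <- predict(model, data, type = "link")
  if (stats::sd(lp) == 0)
    stop("linear predictor is constant; calibration slope unidentifiable")
  fit <- fit_logistic(cbind(lp = lp), y)
  if (!fit$converged)
    stop("logistic calibration did not converge")
  if (anyNA(fit$coef) || any(abs(fit$coef) > 50))
    stop("logistic calibration unstable (possible separation)")
  a <- unname(fit$coef[["(Intercept)"]])
  b <- unname(fit$coef[["lp"]])
  final <- rescale_model(model, a, b, "_m2")
  new_update_result("2", model, final,
                    calibration_intercept = a, calibration_slope = b)
}

## ---- likelihood-ratio test ---------------------------------------------

#' Likelihood-ratio test between nested logistic fits
#'
#' @param loglik_null,loglik_alt Maximized log-likelihoods of the nested
#'   and the extended model.
#' @param df Number of extra parameters (>= 1).
#' @return List of class `lr_test` with `statistic` (twice the
#'   log-likelihood gain, clamped at zero), `df` and `p_value` (upper-tail
#'   chi-square).
#' @export
lr_test <- function(loglik_null, loglik_alt, df) {
  if (df < 1) stop("df must be at least 1")
  if (loglik_alt < loglik_null - 1e-6)
    warning("alternative log-likelihood below null beyond tolerance")
  stat <- max(0, 2 * (loglik_alt - loglik_null))
  structure(list(statistic = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("LR chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

## Screen blocks of columns against a fixed-offset null by LR test.
## blocks: named list of column-name vectors into `x`.
screen_blocks <- function(y, x, offset, blocks) {
  ll0 <- fit_logistic(NULL, y, offset = offset, intercept = FALSE)$loglik
  rows <- lapply(names(blocks), function(bn) {
    cols <- blocks[[bn]]
    fit <- tryCatch(
      fit_logistic(x[, cols, drop = FALSE], y, offset = offset,
                   intercept = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$coef)) {
      warning(sprintf("screening fit failed for term '%s'; skipped", bn))
      return(data.frame(term = bn, statistic = NA_real_,
                        df = length(cols), p_value = NA_real_,
                        estimate = NA_real_, selected = FALSE))
    }
    lt <- lr_test(ll0, fit$loglik, df = length(cols))
    data.frame(term = bn, statistic = lt$statistic, df = lt$df,
               p_value = lt$p_value,
               estimate = unname(fit$coef[1]), selected = FALSE)
  })
  do.call(rbind, rows)
}

## ---- method 3: revision -------------------------------------------------

#' Method 3: model revision
#'
#' After logistic calibration ([method2_logistic_calibration()]), tests
#' whether any individual predictor carries a different effect in the new
#' population. Each model term is offered one at a time on top of the fixed
#' recalibrated linear predictor (`a2 + b2 * LP` entered as an offset) and
#' its deviation is screened by a likelihood-ratio test. Terms significant
#' at `alpha` are then jointly refit in
#' `outcome ~ alpha + beta * LP + sum(gamma_j x_j)`, and the free
#' coefficients are shrunk parameterwise by bootstrap
#' ([parameterwise_shrinkage()]) with the intercept re-estimated afterwards.
#' With no term selected the result collapses to the Method 2 fit.
#'
#' @inheritParams method1_intercept_adjustment
#' @param alpha Significance level of the LR screening, default 0.05.
#' @param shrink Apply parameterwise shrinkage to the free coefficients
#'   (only when at least one deviation is selected).
#' @param B Bootstrap replicates for shrinkage.
#' @param seed Seed for the shrinkage bootstrap.
#' @return An `update_result` with `calibration_intercept`,
#'   `calibration_slope`, `deviations`, `screening` (one row per term) and
#'   `final_model` (original coefficients scaled by the slope, deviations
#'   added to the selected terms).
#' @export
method3_revision <- function(model, data, alpha = 0.05, shrink = TRUE,
                             B = 200, seed = 1L) {
  y <- get_outcome(data)
  m2 <- method2_logistic_calibration(model, data)
  lp <- predict(model, data, type = "link")
  x <- encode_predictors(data, model)
  drop_const <- apply(x, 2, function(v) stats::sd(v) == 0)
  offset <- m2$calibration_intercept + m2$calibration_slope * lp
  blocks <- as.list(setNames(colnames(x), colnames(x)))[!drop_const]
  screening <- screen_blocks(y, x, offset, blocks)
  screening$selected <- !is.na(screening$p_value) & screening$p_value < alpha
  sel <- screening$term[screening$selected]

  xfree <- cbind(lp = lp, x[, sel, drop = FALSE])
  fit <- fit_logistic(xfree, y)
  shr <- NULL
  if (shrink && length(sel)) {
    shr <- shrink_free_fit(y, xfree, fit, B = B, seed = seed)
    fit$coef <- shr$coef
  }
  a <- unname(fit$coef[["(Intercept)"]])
  b <- unname(fit$coef[["lp"]])
  gamma <- fit$coef[sel]

  final <- rescale_model(model, a, b, "_m3")
  for (nm in names(gamma))
    final$terms[[nm]]$coefficient <- final$terms[[nm]]$coefficient + gamma[[nm]]
  new_update_result("3", model, final,
                    calibration_intercept = a, calibration_slope = b,
                    deviations = gamma, screening = screening,
                    shrinkage_factors = shr$factors,
                    internal = list(y = y, design = xfree))
}

## ---- method 4: re-estimation -------------------------------------------

#' Method 4: complete re-estimation
#'
#' Refits intercept and all coefficients of the model's original predictor
#' set by maximum likelihood in the new data, discarding the published
#' estimates, then applies parameterwise shrinkage with intercept
#' re-estimation.
#'
#' @inheritParams method3_revision
#' @return An `update_result` with `refit_coefficients` (post-shrinkage),
#'   their pre-shrinkage values and Wald standard errors (`ml_coefficients`,
#'   `se`), `loglik` of the unshrunk fit, and `final_model`.
#' @export
method4_reestimation <- function(model, data, shrink = TRUE, B = 200,
                                 seed = 1L) {
  y <- get_outcome(data)
  x <- encode_predictors(data, model)
  const <- colnames(x)[apply(x, 2, function(v) stats::sd(v) == 0)]
  if (length(const))
    stop(sprintf("constant design term(s): %s", paste(const, collapse = ", ")))
  fit <- fit_logistic(x, y)
  if (fit$rank < ncol(x) + 1 || anyNA(fit$coef))
    stop(sprintf("design matrix not full rank; term(s): %s",
                 paste(names(fit$coef)[is.na(fit$coef)], collapse = ", ")))
  if (!fit$converged) stop("re-estimation did not converge")
  check_separation(fit$coef, x, "method 4")
  ml_coef <- fit$coef
  se <- sqrt(diag(fit$vcov))
  loglik <- fit$loglik
  shr <- NULL
  if (shrink) {
    shr <- shrink_free_fit(y, x, fit, B = B, seed = seed)
    fit$coef <- shr$coef
  }
  final <- model
  final$name <- paste0(model$name, "_m4")
  final$intercept <- unname(fit$coef[["(Intercept)"]])
  for (nm in names(final$terms))
    final$terms[[nm]]$coefficient <- unname(fit$coef[[nm]])
  new_update_result("4", model, final,
                    refit_coefficients = fit$coef,
                    ml_coefficients = ml_coef, se = se, loglik = loglik,
                    vcov = fit$vcov,
                    shrinkage_factors = shr$factors,
                    internal = list(y = y, design = x))
}

## ---- method 5: extension with new predictors ---------------------------

#' Method 5: extension with new predictors
#'
#' Candidate predictors absent from the original model are screened one
#' block at a time against the fixed recalibrated linear predictor (as in
#' [method3_revision()]; multi-level categoricals are tested and selected
#' as whole blocks). Selected candidates are jointly refit in
#' `outcome ~ alpha + beta * LP + sum(delta_k z_k)` and shrunk
#' parameterwise. With an empty candidate list (or nothing selected) the
#' result collapses to Method 2.
#'
#' @inheritParams method3_revision
#' @param candidates Named list of candidate blocks (see
#'   [method5_candidates()] for the per-model defaults); each block is a
#'   list with a `terms` list of `{name, label, derivation}` entries.
#' @return An `update_result` with `added_terms` (per-term coefficients of
#'   the selected candidates), `screening`, calibration intercept/slope and
#'   `final_model` extended with the new terms.
#' @export
method5_extension <- function(model, data,
                              candidates = method5_candidates(model$name),
                              alpha = 0.05, shrink = TRUE, B = 200,
                              seed = 1L) {
  y <- get_outcome(data)
  m2 <- method2_logistic_calibration(model, data)
  lp <- predict(model, data, type = "link")

  cand_terms <- unlist(lapply(candidates, `[[`, "terms"), recursive = FALSE)
  dup <- intersect(vapply(cand_terms, `[[`, character(1), "name"),
                   names(model$terms))
  if (length(dup))
    stop(sprintf("candidate term(s) already in model '%s': %s",
                 model$name, paste(dup, collapse = ", ")))

  if (!length(candidates)) {
    final <- rescale_model(model, m2$calibration_intercept,
                           m2$calibration_slope, "_m5")
    return(new_update_result("5", model, final,
                             calibration_intercept = m2$calibration_intercept,
                             calibration_slope = m2$calibration_slope,
                             added_terms = numeric(0),
                             screening = data.frame()))
  }

  z <- candidate_design(data, candidates)
  offset <- m2$calibration_intercept + m2$calibration_slope * lp
  screening <- screen_blocks(y, z$x, offset, z$blocks)
  screening$selected <- !is.na(screening$p_value) & screening$p_value < alpha
  sel_blocks <- screening$term[screening$selected]
  sel_cols <- unlist(z$blocks[sel_blocks], use.names = FALSE)

  xfree <- cbind(lp = lp, z$x[, sel_cols, drop = FALSE])
  fit <- fit_logistic(xfree, y)
  shr <- NULL
  if (shrink && length(sel_cols)) {
    shr <- shrink_free_fit(y, xfree, fit, B = B, seed = seed)
    fit$coef <- shr$coef
  }
  a <- unname(fit$coef[["(Intercept)"]])
  b <- unname(fit$coef[["lp"]])
  delta <- fit$coef[sel_cols]

  final <- rescale_model(model, a, b, "_m5")
  for (cn in sel_cols) {
    tm <- z$terms[[cn]]
    tm$coefficient <- unname(delta[[cn]])
    final$terms[[cn]] <- tm
  }
  new_update_result("5", model, final,
                    calibration_intercept = a, calibration_slope = b,
                    added_terms = delta, screening = screening,
                    shrinkage_factors = shr$factors,
                    internal = list(y = y, design = xfree))
}

## ---- de novo development ------------------------------------------------

#' Develop a model by backward stepwise selection
#'
#' Starts from the full logistic model on all candidate blocks and
#' iteratively removes the block with the largest likelihood-ratio p-value
#' at or above `alpha` (multi-level categoricals leave as whole blocks;
#' ties broken toward the block with the smaller largest absolute
#' standardized coefficient) until every remaining block is significant.
#' The retained coefficients are shrunk parameterwise and the intercept
#' re-estimated.
#'
#' @param data Imputed cohort with a 0/1 `outcome`.
#' @param candidates Named list of candidate blocks, default
#'   [development_candidates()].
#' @inheritParams method3_revision
#' @return An `update_result` (method `"developed"`) whose `final_model` is
#'   a standalone [risk_model()] built from the retained terms.
#' @export
develop_model <- function(data, candidates = development_candidates(),
                          alpha = 0.05, shrink = TRUE, B = 200, seed = 1L) {
  y <- get_outcome(data)
  z <- candidate_design(data, candidates)
  current <- names(z$blocks)

  repeat {
    if (!length(current)) break
    cols <- unlist(z$blocks[current], use.names = FALSE)
    full <- fit_logistic(z$x[, cols, drop = FALSE], y)
    stats_tab <- lapply(current, function(bn) {
      rest <- unlist(z$blocks[setdiff(current, bn)], use.names = FALSE)
      red <- fit_logistic(z$x[, rest, drop = FALSE], y)
      lt <- lr_test(red$loglik, full$loglik, df = length(z$blocks[[bn]]))
      zmax <- max(abs(full$coef[z$blocks[[bn]]] /
                        sqrt(diag(full$vcov)[z$blocks[[bn]]])), na.rm = TRUE)
      c(p = lt$p_value, zmax = zmax)
    })
    p <- vapply(stats_tab, `[[`, numeric(1), "p")
    zmax <- vapply(stats_tab, `[[`, numeric(1), "zmax")
    if (max(p) < alpha) break
    worst <- which(p == max(p))
    drop_i <- worst[which.min(zmax[worst])]
    current <- setdiff(current, current[drop_i])
  }

  if (!length(current)) {
    warning("no candidate survived backward selection; intercept-only model")
    fit <- fit_logistic(NULL, y)
    final <- risk_model("developed", unname(fit$coef[["(Intercept)"]]),
                        terms = list(), label = "Developed model")
    return(new_update_result("developed", NULL, final,
                             refit_coefficients = fit$coef,
                             retained = character()))
  }

  cols <- unlist(z$blocks[current], use.names = FALSE)
  xfree <- z$x[, cols, drop = FALSE]
  fit <- fit_logistic(xfree, y)
  shr <- NULL
  if (shrink) {
    shr <- shrink_free_fit(y, xfree, fit, B = B, seed = seed)
    fit$coef <- shr$coef
  }
  terms <- lapply(cols, function(cn) {
    tm <- z$terms[[cn]]
    tm$coefficient <- unname(fit$coef[[cn]])
    tm
  })
  final <- risk_model("developed", unname(fit$coef[["(Intercept)"]]),
                      terms = terms, label = "Developed model")
  new_update_result("developed", NULL, final,
                    refit_coefficients = fit$coef, retained = current,
                    shrinkage_factors = shr$factors,
                    internal = list(y = y, design = xfree))
}
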