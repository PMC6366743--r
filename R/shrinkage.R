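## Bootstrap engine behind parameterwise shrinkage.
## y: 0/1 outcome; x: free-term design (no intercept column);
## fit: full-sample fit from fit_logistic(x, y).
shrink_free_fit <- function(y, x, fit, B = 200, seed = 1L) {
  if (B < 50)
    warning(sprintf("B = %d bootstrap replicates is low; factors will be noisy", B))
  n <- length(y)
  p <- ncol(x)
  set.seed(seed)
  cal <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(x)))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(fit_logistic(x[idx, , drop = FALSE], y[idx]),
                   error = function(e) NULL)
    if (is.null(fb) || !fb$converged || anyNA(fb$coef)) {
      failed <- failed + 1L
      next
    }
    ## per-term linear-predictor contributions of the resample model,
    ## evaluated on the original sample
    contrib <- sweep(x, 2, fb$coef[colnames(x)], `*`)
    keep <- apply(contrib, 2, function(v) stats::sd(v) > 0)
    cb <- tryCatch(
      fit_logistic(contrib[, keep, drop = FALSE], y)$coef[colnames(contrib)[keep]],
      error = function(e) NULL)
    if (is.null(cb)) {
      failed <- failed + 1L
      next
    }
    cal[b, names(cb)] <- cb
  }
  if (failed)
    warning(sprintf("%d of %d shrinkage resamples failed and were skipped",
                    failed, B))
  factors <- colMeans(cal, na.rm = TRUE)
  factors[is.nan(factors)] <- 1
  factors <- pmin(pmax(factors, 0), 1.5)
  shrunk <- fit$coef[colnames(x)] * factors
  ## re-estimate the intercept with the shrunk terms as offset, restoring
  ## perfect mean calibration (training E/O = 1) of the shrunk model
  off <- drop(x %*% shrunk)
  a <- fit_logistic(NULL, y, offset = off)$coef[["(Intercept)"]]
  list(factors = factors,
       coef = c("(Intercept)" = unname(a), shrunk),
       n_failed = failed)
}

#' Parameterwise bootstrap shrinkage
#'
#' Shrinks the free coefficients of an updated model to correct for
#' overfitting. For each of `B` bootstrap resamples the free model is
#' refit, its per-term linear-predictor contributions are evaluated on the
#' original sample, and a logistic calibration regression of the original
#' outcome on those contributions yields one calibration coefficient per
#' term; the per-term bootstrap means are the shrinkage factors (truncated
#' to `[0, 1.5]`). Coefficients are multiplied by their factors and the
#' intercept is then re-estimated by maximum likelihood with all shrunk
#' terms entered as an offset, so the shrunk model keeps training E/O = 1.
#'
#' Methods 3-5 and [develop_model()] apply this internally
#' (`shrink = TRUE`); this function re-applies it to a fit produced with
#' `shrink = FALSE`, e.g. to inspect factor stability across `B` or seeds.
#'
#' @param fit An `update_result` with free coefficients (Methods 3-5 or a
#'   developed model).
#' @param data Unused; the fit carries its own training design.
#' @param B Bootstrap replicates (a warning is issued below 50).
#' @param seed Integer seed for the resampling.
#' @return The `update_result` with shrunk coefficients, updated
#'   `final_model` and `shrinkage_factors`.
#' @export
parameterwise_shrinkage <- function(fit, data = NULL, B = 200, seed = 1L) {
  if (!inherits(fit, "update_result"))
    stop("fit must be an update_result")
  if (is.null(fit$internal))
    stop("this update_result has no free coefficients to shrink")
  y <- fit$internal$y
  x <- fit$internal$design
  base_fit <- fit_logistic(x, y)
  shr <- shrink_free_fit(y, x, base_fit, B = B, seed = seed)
  cf <- shr$coef
  fit$shrinkage_factors <- shr$factors

  if (fit$method %in% c("3", "5")) {
    a <- unname(cf[["(Intercept)"]])
    b <- unname(cf[["lp"]])
    extra <- cf[setdiff(names(cf), c("(Intercept)", "lp"))]
    final <- rescale_model(fit$base_model, a, b, paste0("_m", fit$method))
    for (nm in names(extra)) {
      if (nm %in% names(final$terms)) {
        final$terms[[nm]]$coefficient <-
          final$terms[[nm]]$coefficient + extra[[nm]]
      } else {
        tm <- fit$final_model$terms[[nm]]
        tm$coefficient <- unname(extra[[nm]])
        final$terms[[nm]] <- tm
      }
    }
    fit$calibration_intercept <- a
    fit$calibration_slope <- b
    if (fit$method == "3") fit$deviations <- extra else fit$added_terms <- extra
    fit$final_model <- final
  } else {
    final <- fit$final_model
    final$intercept <- unname(cf[["(Intercept)"]])
    for (nm in names(final$terms))
      final$terms[[nm]]$coefficient <- unname(cf[[nm]])
    fit$refit_coefficients <- cf
    fit$final_model <- final
  }
  fit
}
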