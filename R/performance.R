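#' Concordance (C) statistic with DeLong confidence interval
#'
#' Proportion of event/non-event pairs in which the event carries the
#' higher predicted risk, ties counted one half (the area under the ROC
#' curve). The confidence interval uses the asymptotic rank-based variance
#' of DeLong et al. computed from placement values.
#'
#' @param probs Predicted probabilities (any monotone score works).
#' @param outcomes 0/1 outcomes, both classes present.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `estimate`, `se` and `ci` (length-2 vector, clipped to
#'   `[0, 1]`).
#' @export
c_statistic <- function(probs, outcomes, conf_level = 0.95) {
  stopifnot(length(probs) == length(outcomes))
  y <- as.numeric(outcomes)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present")
  r <- rank(probs)
  est <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ## placement values: for each event, the fraction of non-events it beats
  pe <- probs[y == 1]
  pn <- probs[y == 0]
  cmp <- outer(pe, pn, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(est + c(-1, 1) * zq * se, 0), 1)
  list(estimate = est, se = se, ci = ci)
}

#' Expected/observed event ratio
#'
#' Sum of predicted probabilities (expected events, E) over the observed
#' event count (O). 1 indicates perfect mean calibration, values below 1
#' under-prediction of the event total.
#'
#' @inheritParams c_statistic
#' @return The ratio E/O.
#' @export
eo_ratio <- function(probs, outcomes) {
  stopifnot(length(probs) == length(outcomes))
  o <- sum(outcomes)
  if (o == 0) stop("no observed events; E/O undefined")
  sum(probs) / o
}

#' Poisson confidence interval for an E/O ratio
#'
#' Treats the observed event count as Poisson. The default closed form is
#' the log-scale normal approximation
#' `ratio * exp(-z / sqrt(O))` to `ratio * exp(+z / sqrt(O))`;
#' `exact = TRUE` instead uses exact chi-square Poisson bounds on O.
#'
#' @param ratio E/O ratio, positive.
#' @param observed Observed event count O, at least 1.
#' @param conf_level Confidence level, default 0.95.
#' @param exact Use exact Poisson (chi-square) bounds for O.
#' @return Length-2 vector `c(lower, upper)`.
#' @export
eo_confidence_interval <- function(ratio, observed, conf_level = 0.95,
                                   exact = FALSE) {
  if (observed < 1) stop("observed event count must be at least 1")
  if (ratio <= 0) stop("ratio must be positive")
  alpha <- 1 - conf_level
  if (exact) {
    o_lo <- stats::qchisq(alpha / 2, 2 * observed) / 2
    o_hi <- stats::qchisq(1 - alpha / 2, 2 * (observed + 1)) / 2
    e <- ratio * observed
    return(c(e / o_hi, e / o_lo))
  }
  zq <- stats::qnorm(1 - alpha / 2)
  ratio * exp(c(-1, 1) * zq / sqrt(observed))
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the 0/1
#' outcome; 0 for perfect prediction, bounded by 1.
#'
#' @inheritParams c_statistic
#' @return Scalar in `[0, 1]`.
#' @export
brier_score <- function(probs, outcomes) {
  stopifnot(length(probs) == length(outcomes))
  mean((probs - outcomes)^2)
}

#' Yates slope
#'
#' Mean predicted risk among events minus mean predicted risk among
#' non-events; larger is better.
#'
#' @inheritParams c_statistic
#' @return Scalar in `[-1, 1]`.
#' @export
yates_slope <- function(probs, outcomes) {
  stopifnot(length(probs) == length(outcomes))
  y <- as.numeric(outcomes)
  if (!any(y == 1) || !any(y == 0))
    stop("both outcome classes must be present")
  mean(probs[y == 1]) - mean(probs[y == 0])
}

#' Calibration curve over risk deciles
#'
#' Bins records by quantiles of predicted risk (deciles by default) and
#' reports mean predicted risk against the observed event proportion per
#' bin. Bins with identical quantile boundaries (e.g. constant
#' predictions) are merged with a warning.
#'
#' @inheritParams c_statistic
#' @param n_bins Number of quantile bins, default 10.
#' @return Data frame of class `calibration_curve`: `bin`, `n`,
#'   `mean_predicted`, `observed_proportion`.
#' @export
calibration_curve <- function(probs, outcomes, n_bins = 10) {
  stopifnot(length(probs) == length(outcomes))
  if (length(probs) < n_bins)
    stop("need at least one record per requested bin")
  breaks <- stats::quantile(probs, probs = seq(0, 1, length.out = n_bins + 1))
  ub <- unique(breaks)
  if (length(ub) < length(breaks))
    warning("fewer distinct risk levels than bins; bins merged")
  if (length(ub) == 1) {
    out <- data.frame(bin = 1L, n = length(probs),
                      mean_predicted = mean(probs),
                      observed_proportion = mean(outcomes))
    class(out) <- c("calibration_curve", class(out))
    return(out)
  }
  grp <- cut(probs, breaks = ub, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    data.frame(bin = g, n = sum(sel), mean_predicted = mean(probs[sel]),
               observed_proportion = mean(outcomes[sel]))
  }))
  rownames(out) <- NULL
  class(out) <- c("calibration_curve", class(out))
  out
}

#' Full discrimination and calibration report
#'
#' Bundles every performance measure for one probability/outcome pairing:
#' C-statistic (DeLong CI), E/O ratio (Poisson CI), Brier score, Yates
#' slope, together with the event counts behind them.
#'
#' @inheritParams c_statistic
#' @return List of class `performance_report`: `n`, `events` (O),
#'   `expected_events` (E), `eo_ratio` with `eo_ci`, `brier`,
#'   `yates_slope`, `c_statistic` with `c_ci`.
#' @export
performance_report <- function(probs, outcomes, conf_level = 0.95) {
  y <- as.numeric(outcomes)
  cs <- c_statistic(probs, y, conf_level)
  eo <- eo_ratio(probs, y)
  structure(list(
    n = length(y), events = sum(y), expected_events = sum(probs),
    eo_ratio = eo,
    eo_ci = eo_confidence_interval(eo, sum(y), conf_level),
    brier = brier_score(probs, y),
    yates_slope = yates_slope(probs, y),
    c_statistic = cs$estimate, c_ci = cs$ci),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("n = %d, O = %d, E = %.1f\n", x$n, x$events, x$expected_events))
  cat(sprintf("  E/O:    %.2f (%.2f-%.2f)\n", x$eo_ratio, x$eo_ci[1],
              x$eo_ci[2]))
  cat(sprintf("  C:      %.2f (%.2f-%.2f)\n", x$c_statistic, x$c_ci[1],
              x$c_ci[2]))
  cat(sprintf("  Brier:  %.3f\n  Yates:  %.3f\n", x$brier, x$yates_slope))
  invisible(x)
}
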