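`%||%` <- function(x, y) if (is.null(x)) y else x

logit <- function(p) log(p / (1 - p))

## Relative-deviance convergence tolerance and iteration cap for all
## internal logistic fits (IRLS via stats::glm.fit).
.glm_control <- function() stats::glm.control(epsilon = 1e-10, maxit = 100)

## Logistic ML fit on a plain design matrix. `x` must NOT contain an
## intercept column; one is prepended unless intercept = FALSE.
## Returns coefficients, fitted values, log-likelihood and (X'WX)^-1.
fit_logistic <- function(x, y, offset = NULL, intercept = TRUE) {
  n <- length(y)
  if (is.null(x)) {
    xm <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    xm <- as.matrix(x)
  }
  if (intercept) xm <- cbind("(Intercept)" = rep(1, n), xm)
  if (ncol(xm) == 0L) {
    ## offset-only model: nothing to estimate
    p <- stats::plogis(offset %||% rep(0, n))
    return(list(coef = numeric(0), fitted = p,
                loglik = sum(stats::dbinom(y, 1, p, log = TRUE)),
                converged = TRUE, vcov = matrix(0, 0, 0), rank = 0L))
  }
  fit <- suppressWarnings(stats::glm.fit(
    xm, y, family = stats::binomial(),
    offset = offset %||% rep(0, n),
    control = .glm_control()))
  cf <- fit$coefficients
  p <- fit$fitted.values
  ll <- sum(stats::dbinom(y, 1, p, log = TRUE))
  vc <- matrix(NA_real_, ncol(xm), ncol(xm),
               dimnames = list(colnames(xm), colnames(xm)))
  ok <- seq_len(fit$rank)
  if (fit$rank > 0) {
    r <- fit$qr$qr[ok, ok, drop = FALSE]
    r[lower.tri(r)] <- 0
    vc_ok <- chol2inv(r)
    piv <- fit$qr$pivot[ok]
    vc[piv, piv] <- vc_ok
  }
  list(coef = cf, fitted = p, loglik = ll, converged = fit$converged,
       vcov = vc, rank = fit$rank)
}

## Indicator columns fitted with |coef| beyond this are treated as
## (quasi-)separated.
.separation_limit <- 15

is_indicator_col <- function(x) all(x %in% c(0, 1))

check_separation <- function(coef, x, context) {
  coef <- coef[setdiff(names(coef), "(Intercept)")]
  if (!length(coef)) return(invisible(NULL))
  bad <- vapply(names(coef), function(nm) {
    !is.na(coef[[nm]]) && abs(coef[[nm]]) > .separation_limit &&
      is_indicator_col(x[, nm])
  }, logical(1))
  if (any(bad)) {
    stop(sprintf("%s: separation detected for term(s) %s",
                 context, paste(names(coef)[bad], collapse = ", ")),
         call. = FALSE)
  }
  invisible(NULL)
}
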