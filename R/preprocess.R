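#' Exclude previously diagnosed participants
#'
#' Participants with a prior diabetes diagnosis never undergo the screening
#' test and are removed before any analysis; record order is preserved.
#'
#' @param cohort Cohort data frame with a `previously_diagnosed` column.
#' @return The non-flagged records.
#' @export
exclude_diagnosed <- function(cohort) {
  if (is.null(cohort$previously_diagnosed) ||
      anyNA(cohort$previously_diagnosed))
    stop("previously_diagnosed flag must be present on all records")
  cohort[cohort$previously_diagnosed == 0, , drop = FALSE]
}

## Reference levels used to break ties in mode imputation.
.reference_levels <- c(smoking = "never", drinking = "never",
                       education = "primary")

#' Simple (mean / mode) imputation
#'
#' Continuous fields get the mean of their observed values; binary and
#' categorical fields get the observed mode, with ties broken toward the
#' reference level (0 for flags; `never` for smoking/drinking, `primary`
#' for education). Observed values are never altered, so the post-imputation
#' mean of a continuous field equals the mean of its observed values
#' exactly.
#'
#' @param cohort Cohort data frame.
#' @return The cohort with no missing values left.
#' @export
simple_impute <- function(cohort) {
  for (f in names(cohort)) {
    v <- cohort[[f]]
    if (!anyNA(v)) next
    obs <- v[!is.na(v)]
    if (!length(obs))
      stop(sprintf("field '%s' is fully missing; cannot impute", f))
    if (is.numeric(obs) && !all(obs %in% c(0, 1))) {
      fill <- mean(obs)
    } else {
      tab <- table(obs)
      top <- names(tab)[tab == max(tab)]
      ref <- if (is.numeric(obs)) "0" else
        unname(.reference_levels[f]) %||% sort(top)[1]
      fill <- if (ref %in% top) ref else sort(top)[1]
      if (is.numeric(obs)) fill <- as.numeric(fill)
    }
    v[is.na(v)] <- fill
    cohort[[f]] <- v
  }
  cohort
}

#' Random train/test split
#'
#' Simple random split without outcome stratification; `round(fraction * n)`
#' records go to the training set.
#'
#' @param cohort Cohort data frame, at least two rows.
#' @param fraction Training fraction, strictly inside (0, 1); default 2/3.
#' @param seed Integer seed making the partition reproducible.
#' @return List of class `split_cohort` with elements `train`, `test`,
#'   `fraction` and `seed`.
#' @export
split_cohort <- function(cohort, fraction = 2 / 3, seed = 1L) {
  n <- nrow(cohort)
  if (n < 2) stop("need at least two records to split")
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly inside (0, 1)")
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train > n - 1)
    stop("degenerate split: one side would be empty")
  set.seed(seed)
  idx <- sample.int(n, n_train)
  structure(list(train = cohort[sort(idx), , drop = FALSE],
                 test = cohort[-sort(idx), , drop = FALSE],
                 fraction = fraction, seed = seed),
            class = "split_cohort")
}

#' @export
print.split_cohort <- function(x, ...) {
  cat(sprintf("<split_cohort> train %d / test %d (fraction %.4f, seed %s)\n",
              nrow(x$train), nrow(x$test), x$fraction, x$seed))
  invisible(x)
}
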