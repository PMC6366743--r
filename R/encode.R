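## Derivation rules: each maps raw cohort fields to one design column.
## Registered here so model validation can reject unknown types early.
.derivation_types <- function() {
  list(
    sex = function(d, dv) as.numeric(d$sex == dv$level),
    continuous = function(d, dv) as.numeric(d[[dv$field]]),
    range = function(d, dv) {
      x <- d[[dv$field]]
      lo <- dv$min %||% -Inf
      hi <- dv$max %||% Inf
      lo_ok <- if (isTRUE(dv$min_open)) x > lo else x >= lo
      as.numeric(lo_ok & x < hi)
    },
    age_increments = function(d, dv) {
      x <- d[[dv$field %||% "age"]]
      k <- floor((x - dv$start) / dv$step) + 1
      pmin(pmax(k, 0), dv$cap)
    },
    waist_sex_cutoff = function(d, dv) {
      cut <- ifelse(d$sex == "male", dv$male, dv$female)
      as.numeric(d$waist >= cut)
    },
    waist_sex_range = function(d, dv) {
      lo <- ifelse(d$sex == "male", dv$male_min, dv$female_min)
      hi <- ifelse(d$sex == "male", dv$male_max, dv$female_max)
      as.numeric(d$waist >= lo & d$waist < hi)
    },
    bp_either = function(d, dv) as.numeric(d$sbp >= dv$sbp | d$dbp >= dv$dbp),
    flag = function(d, dv) as.numeric(d[[dv$field]]),
    level = function(d, dv) as.numeric(d[[dv$field]] == dv$level),
    family_history = function(d, dv) {
      parent <- d$fh_mother == 1 | d$fh_father == 1
      sibling <- d$fh_sister == 1 | d$fh_brother == 1
      as.numeric(switch(dv$rule,
        parent = parent,
        sibling = sibling,
        parent_or_sibling = parent | sibling,
        parent_and_sibling = parent & sibling,
        stop(sprintf("unknown family-history rule '%s'", dv$rule))))
    }
  )
}

## Raw cohort fields a derivation reads (for missing-value checks).
derivation_fields <- function(dv) {
  switch(dv$type,
    sex = "sex",
    continuous = dv$field,
    range = dv$field,
    age_increments = dv$field %||% "age",
    waist_sex_cutoff = c("sex", "waist"),
    waist_sex_range = c("sex", "waist"),
    bp_either = c("sbp", "dbp"),
    flag = dv$field,
    level = dv$field,
    family_history = c("fh_mother", "fh_father", "fh_sister", "fh_brother"))
}

encode_term <- function(cohort, derivation) {
  fn <- .derivation_types()[[derivation$type]]
  if (is.null(fn)) stop(sprintf("unknown derivation type '%s'", derivation$type))
  fn(cohort, derivation)
}

#' Encode raw participant records as model design terms
#'
#' Applies every derivation rule of `model` to the rows of `cohort`,
#' producing one design column per model term (band memberships as mutually
#' exclusive 0/1 indicators, continuous terms in their native units).
#' Missing values in any required raw field are an error: imputation
#' ([simple_impute()]) must run first.
#'
#' @param cohort Data frame of participant records (see [generate_cohort()]
#'   for the column layout).
#' @param model A [risk_model()].
#' @return Numeric matrix, `nrow(cohort)` rows, one named column per term.
#' @export
encode_predictors <- function(cohort, model) {
  cohort <- as.data.frame(cohort)
  needed <- unique(unlist(lapply(model$terms,
                                 function(tm) derivation_fields(tm$derivation))))
  for (fld in needed) {
    if (is.null(cohort[[fld]]))
      stop(sprintf("required raw field '%s' is absent", fld))
    if (anyNA(cohort[[fld]]))
      stop(sprintf(
        "raw field '%s' has missing values; impute before encoding", fld))
  }
  if (!length(model$terms))
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0))
  cols <- lapply(model$terms, function(tm) encode_term(cohort, tm$derivation))
  x <- do.call(cbind, c(cols, list(deparse.level = 0)))
  colnames(x) <- names(model$terms)
  x
}

#' Linear predictor of a risk model
#'
#' `intercept + sum(coefficient * term value)` on the log-odds scale.
#'
#' @param features Numeric matrix (or named vector for one record) of
#'   encoded term values, as produced by [encode_predictors()]; must cover
#'   every model term.
#' @param model A [risk_model()].
#' @return Numeric vector of log-odds.
#' @export
linear_predictor <- function(features, model) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  beta <- coef(model)
  if (!length(beta)) {
    lp <- rep(model$intercept, nrow(features))
    return(lp)
  }
  missing <- setdiff(names(beta), colnames(features))
  if (length(missing))
    stop(sprintf("feature matrix lacks model term(s): %s",
                 paste(missing, collapse = ", ")))
  lp <- model$intercept + drop(features[, names(beta), drop = FALSE] %*% beta)
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  unname(lp)
}

#' Convert log-odds to predicted risk
#'
#' The inverse-logit transform `1 / (1 + exp(-lp))`; strictly inside (0, 1)
#' for finite input and monotone increasing.
#'
#' @param lp Numeric vector of log-odds.
#' @return Predicted probabilities.
#' @export
predict_risk <- function(lp) {
  if (any(!is.finite(lp))) stop("linear predictor must be finite")
  stats::plogis(lp)
}

#' Predict from a risk model on raw records
#'
#' Convenience wrapper chaining [encode_predictors()], [linear_predictor()]
#' and [predict_risk()].
#'
#' @param object A `risk_model`.
#' @param newdata Data frame of participant records.
#' @param type `"response"` for probabilities, `"link"` for log-odds.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.risk_model <- function(object, newdata,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  lp <- linear_predictor(encode_predictors(newdata, object), object)
  if (type == "link") lp else predict_risk(lp)
}
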