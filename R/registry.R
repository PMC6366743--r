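#' Construct a declarative logistic risk model
#'
#' A `risk_model` is a logistic prediction model stored declaratively: an
#' intercept on the log-odds scale, plus a list of terms, each carrying its
#' published coefficient and a *derivation rule* that maps raw participant
#' fields (age, sex, BMI, waist circumference, blood pressure, medication and
#' family-history flags, smoking) to the 0/1 indicator or continuous value
#' entering the linear predictor. Storing the derivation alongside the
#' coefficient makes a model applicable to any cohort table without
#' hand-building a design matrix.
#'
#' Supported derivation types:
#' \describe{
#'   \item{`sex`}{indicator for `level` (`"male"`/`"female"`).}
#'   \item{`continuous`}{the raw value of `field`.}
#'   \item{`range`}{indicator for `min <= field < max` (`min` inclusive
#'     unless `min_open`; `max` always exclusive, defaulting to `Inf`), the
#'     encoding used for age, BMI and waist bands.}
#'   \item{`age_increments`}{count of completed `step`-year increments at or
#'     above `start`, capped at `cap` (the Rotterdam "age per 5 years from
#'     55" term: 0 below 55, 1 at 55, 2 at 60, ..., capped at 5).}
#'   \item{`waist_sex_cutoff` / `waist_sex_range`}{sex-specific waist
#'     circumference cutoff or band.}
#'   \item{`bp_either`}{indicator for SBP >= `sbp` and/or DBP >= `dbp`.}
#'   \item{`flag`}{a raw 0/1 field (medication use etc.).}
#'   \item{`level`}{indicator for `field == level` (smoking, drinking,
#'     education categories).}
#'   \item{`family_history`}{composites of the four relative flags: `parent`
#'     = mother or father, `sibling` = sister or brother, plus
#'     `parent_or_sibling` and `parent_and_sibling`.}
#' }
#'
#' @param name Identifier (used as list key and in reports).
#' @param intercept Model intercept (log-odds), finite.
#' @param terms List of term objects, each a list with elements `name`,
#'   `coefficient`, `derivation` and optionally `label` and `band` (band
#'   family id for mutually exclusive indicator sets).
#' @param label Human-readable model name.
#' @param fixed_zero_terms Character vector of predictor names assumed 0 for
#'   every participant (e.g. the Finnish model's history of high blood
#'   glucose, unobservable in a screening setting); recorded for provenance,
#'   they contribute nothing to the linear predictor.
#' @return An object of class `risk_model`.
#' @seealso [load_model_registry()], [linear_predictor()], [predict_risk()]
#' @export
risk_model <- function(name, intercept, terms, label = name,
                       fixed_zero_terms = character()) {
  if (!is.numeric(intercept) || length(intercept) != 1 || !is.finite(intercept))
    stop(sprintf("model '%s': intercept must be a finite number", name))
  seen <- character()
  for (tm in terms) {
    for (fld in c("name", "coefficient", "derivation")) {
      if (is.null(tm[[fld]]))
        stop(sprintf("model '%s': term '%s' is missing '%s'",
                     name, tm$name %||% "<unnamed>", fld))
    }
    if (!is.numeric(tm$coefficient) || !is.finite(tm$coefficient))
      stop(sprintf("model '%s': coefficient for term '%s' must be finite",
                   name, tm$name))
    if (is.null(tm$derivation$type) ||
        !tm$derivation$type %in% names(.derivation_types()))
      stop(sprintf("model '%s': term '%s' has unknown derivation type '%s'",
                   name, tm$name, tm$derivation$type %||% "<missing>"))
    if (tm$name %in% seen)
      stop(sprintf("model '%s': duplicate term '%s'", name, tm$name))
    seen <- c(seen, tm$name)
  }
  names(terms) <- vapply(terms, `[[`, character(1), "name")
  structure(list(name = name, label = label, intercept = intercept,
                 terms = terms,
                 fixed_zero_terms = as.character(fixed_zero_terms)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s (%s)\n", x$name, x$label))
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  for (tm in x$terms)
    cat(sprintf("  %-24s %8.4f  [%s]\n", tm$name, tm$coefficient,
                tm$derivation$type))
  if (length(x$fixed_zero_terms))
    cat("  fixed at zero:", paste(x$fixed_zero_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Coefficients of a risk model
#'
#' @param object A `risk_model`.
#' @param ... Unused.
#' @return Named numeric vector of term coefficients (intercept excluded;
#'   see `object$intercept`).
#' @export
coef.risk_model <- function(object, ...) {
  vapply(object$terms, `[[`, numeric(1), "coefficient")
}

#' Load a model registry
#'
#' Reads a JSON document of declarative logistic risk models. The bundled
#' registry (the default `source`) contains the five published
#' prevalent-diabetes models — Cambridge, Kuwaiti, Omani, Rotterdam and
#' simplified Finnish — with their original published intercepts and
#' coefficients.
#'
#' @param source Path to a registry JSON file.
#' @return Named list of [risk_model()] objects, class `model_registry`.
#' @examples
#' reg <- load_model_registry()
#' reg$cambridge$intercept   # -6.322
#' @export
load_model_registry <- function(source = bundled_registry_path()) {
  doc <- tryCatch(jsonlite::read_json(source, simplifyVector = FALSE),
                  error = function(e) stop(sprintf(
                    "failed to parse model registry '%s': %s",
                    source, conditionMessage(e)), call. = FALSE))
  models <- lapply(names(doc), function(nm) {
    entry <- doc[[nm]]
    terms <- lapply(entry$terms, function(tm) {
      tm$coefficient <- as.numeric(tm$coefficient %||% NA_real_)
      tm
    })
    risk_model(name = nm,
               intercept = as.numeric(entry$intercept %||% NA_real_),
               terms = terms,
               label = entry$label %||% nm,
               fixed_zero_terms = unlist(entry$fixed_zero_terms) %||% character())
  })
  names(models) <- names(doc)
  structure(models, class = "model_registry")
}

#' @export
print.model_registry <- function(x, ...) {
  cat(sprintf("<model_registry> %d models: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Serialize a model registry to JSON
#'
#' Inverse of [load_model_registry()]: reloading the written file yields
#' identical intercepts and coefficients.
#'
#' @param registry A `model_registry` (or plain named list of `risk_model`s).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_registry <- function(registry, path) {
  doc <- lapply(registry, function(m) {
    out <- list(label = m$label, intercept = m$intercept,
                terms = unname(m$terms))
    if (length(m$fixed_zero_terms))
      out$fixed_zero_terms <- as.list(m$fixed_zero_terms)
    out
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Path to the bundled registry of five published diabetes risk models
#' @return File path within the installed package.
#' @export
bundled_registry_path <- function() {
  system.file("extdata", "model_registry.json", package = "riskupdate",
              mustWork = TRUE)
}
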