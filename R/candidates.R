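## Candidate predictor blocks for model extension (Method 5) and de novo
## development. A block groups the indicator terms of one predictor; multi-
## level categoricals (education, smoking, drinking, the BMI bands) are
## screened and selected as whole blocks.

cand_block <- function(name, label, terms) {
  names(terms) <- vapply(terms, `[[`, character(1), "name")
  list(name = name, label = label, terms = terms)
}

cand_term <- function(name, label, derivation) {
  list(name = name, label = label, derivation = derivation)
}

#' Candidate predictor pool
#'
#' All predictors measured in the screening study, as selectable blocks:
#' sex, age (continuous), the BMI 25-30 / >=30 band pair, SBP, DBP, the
#' sex-specific waist cutoff (>=94 cm men / >=80 cm women), education,
#' antihypertensive / lipid-lowering / corticosteroid use, combined
#' parent-and-sibling diabetes history, smoking and drinking status.
#'
#' @return Named list of candidate blocks.
#' @export
candidate_pool <- function() {
  blocks <- list(
    cand_block("sex_male", "Male gender",
               list(cand_term("male", "Male gender",
                              list(type = "sex", level = "male")))),
    cand_block("age", "Age (years)",
               list(cand_term("age", "Age (years)",
                              list(type = "continuous", field = "age")))),
    cand_block("bmi_cat", "BMI category", list(
      cand_term("bmi_25_30", "25 <= BMI < 30 kg/m2",
                list(type = "range", field = "bmi", min = 25, max = 30)),
      cand_term("bmi_30", "BMI >= 30 kg/m2",
                list(type = "range", field = "bmi", min = 30)))),
    cand_block("sbp", "Systolic blood pressure (mmHg)",
               list(cand_term("sbp", "Systolic blood pressure",
                              list(type = "continuous", field = "sbp")))),
    cand_block("dbp", "Diastolic blood pressure (mmHg)",
               list(cand_term("dbp", "Diastolic blood pressure",
                              list(type = "continuous", field = "dbp")))),
    cand_block("wc_sex_high", "WC >= 94 cm (M) / >= 80 cm (W)",
               list(cand_term("wc_sex_high", "WC >= 94 cm (M) / >= 80 cm (W)",
                              list(type = "waist_sex_cutoff",
                                   male = 94, female = 80)))),
    cand_block("education", "Highest education", list(
      cand_term("edu_high_school", "High school",
                list(type = "level", field = "education",
                     level = "high_school")),
      cand_term("edu_university", "University",
                list(type = "level", field = "education",
                     level = "university")))),
    cand_block("antihypertensive", "Use of antihypertensive medication",
               list(cand_term("antihypertensive",
                              "Use of antihypertensive medication",
                              list(type = "flag",
                                   field = "antihypertensive")))),
    cand_block("lipid_lowering", "Use of lipid-lowering medication",
               list(cand_term("lipid_lowering",
                              "Use of lipid-lowering medication",
                              list(type = "flag", field = "lipid_lowering")))),
    cand_block("corticosteroids", "Use of corticosteroids",
               list(cand_term("corticosteroids", "Use of corticosteroids",
                              list(type = "flag",
                                   field = "corticosteroids")))),
    cand_block("fh_parent_and_sibling", "Parent and sibling has diabetes",
               list(cand_term("fh_parent_and_sibling",
                              "Parent and sibling has diabetes",
                              list(type = "family_history",
                                   rule = "parent_and_sibling")))),
    cand_block("smoking", "Smoking status", list(
      cand_term("smoking_ex", "Ex-smoker",
                list(type = "level", field = "smoking", level = "ex")),
      cand_term("smoking_current", "Current smoker",
                list(type = "level", field = "smoking", level = "current")))),
    cand_block("drinking", "Drinking status", list(
      cand_term("drinking_ex", "Ex-drinker",
                list(type = "level", field = "drinking", level = "ex")),
      cand_term("drinking_current", "Current drinker",
                list(type = "level", field = "drinking",
                     level = "current")))))
  names(blocks) <- vapply(blocks, `[[`, character(1), "name")
  blocks
}

## Per-model Method 5 candidate lists: every measured predictor not already
## present in the model in some form.
.method5_lists <- list(
  cambridge = c("sbp", "dbp", "education", "lipid_lowering", "drinking",
                "wc_sex_high"),
  kuwaiti = c("sex_male", "bmi_cat", "sbp", "dbp", "education",
              "lipid_lowering", "corticosteroids", "smoking", "drinking"),
  omani = c("sex_male", "education", "lipid_lowering", "corticosteroids",
            "smoking", "drinking"),
  rotterdam = c("sbp", "dbp", "education", "lipid_lowering",
                "corticosteroids", "fh_parent_and_sibling", "smoking",
                "drinking", "wc_sex_high"),
  finnish = c("sex_male", "sbp", "dbp", "education", "lipid_lowering",
              "corticosteroids", "fh_parent_and_sibling", "smoking",
              "drinking"))

#' Default Method 5 candidates for a registry model
#'
#' The predictors offered to each published model for extension: everything
#' measured in the study that the model does not already include in some
#' form.
#'
#' @param model_name One of the bundled registry names (`"cambridge"`,
#'   `"kuwaiti"`, `"omani"`, `"rotterdam"`, `"finnish"`).
#' @return Named list of candidate blocks from [candidate_pool()].
#' @export
method5_candidates <- function(model_name) {
  lst <- .method5_lists[[model_name]]
  if (is.null(lst))
    stop(sprintf("no default candidate list for model '%s'", model_name))
  candidate_pool()[lst]
}

#' Candidate predictors for de novo model development
#'
#' The full measured-predictor pool offered to backward stepwise selection.
#'
#' @return Named list of candidate blocks.
#' @export
development_candidates <- function() candidate_pool()

## Encode candidate blocks into one design matrix.
## Returns x (matrix), blocks (block -> column names), terms (per column).
candidate_design <- function(data, candidates) {
  terms <- list()
  cols <- list()
  blocks <- list()
  for (blk in candidates) {
    cn <- character()
    for (tm in blk$terms) {
      fields <- derivation_fields(tm$derivation)
      for (fld in fields) {
        if (is.null(data[[fld]]))
          stop(sprintf("candidate '%s' needs absent raw field '%s'",
                       tm$name, fld))
        if (anyNA(data[[fld]]))
          stop(sprintf("raw field '%s' has missing values; impute first", fld))
      }
      cols[[tm$name]] <- encode_term(data, tm$derivation)
      terms[[tm$name]] <- tm
      cn <- c(cn, tm$name)
    }
    blocks[[blk$name]] <- cn
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  list(x = x, blocks = blocks, terms = terms)
}
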