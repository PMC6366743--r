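#' Configuration for a full updating experiment
#'
#' @param models Character vector of registry model names, or `"all"`.
#' @param methods Integer vector of updating methods to run (subset of
#'   0:5); Method 0 is the unadjusted external validation on the full
#'   analysis set.
#' @param include_developed Also develop a de novo model on the training
#'   split.
#' @param cohort A [cohort_config()] for synthetic data, or a CSV path via
#'   `cohort_csv`.
#' @param cohort_csv Optional path to a cohort CSV (overrides `cohort`).
#' @param registry A model registry; default the bundled five models.
#' @param alpha Significance level for LR screening and stepwise removal.
#' @param split_fraction Training fraction of the 2/3-1/3 split.
#' @param shrinkage_B Bootstrap replicates for parameterwise shrinkage.
#' @param seeds Named list of integer seeds: `cohort`, `split`,
#'   `bootstrap`.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(models = "all", methods = 0:5,
                              include_developed = TRUE,
                              cohort = cohort_config(), cohort_csv = NULL,
                              registry = NULL, alpha = 0.05,
                              split_fraction = 2 / 3, shrinkage_B = 200,
                              seeds = list(cohort = 1L, split = 2L,
                                           bootstrap = 3L)) {
  structure(list(models = models, methods = methods,
                 include_developed = include_developed, cohort = cohort,
                 cohort_csv = cohort_csv, registry = registry, alpha = alpha,
                 split_fraction = split_fraction, shrinkage_B = shrinkage_B,
                 seeds = seeds),
            class = "experiment_config")
}

perf_row <- function(model, method, dataset, probs, outcomes) {
  r <- performance_report(probs, outcomes)
  data.frame(model = model, method = method, dataset = dataset,
             n = r$n, events = r$events, expected = r$expected_events,
             eo = r$eo_ratio, eo_lo = r$eo_ci[1], eo_hi = r$eo_ci[2],
             brier = r$brier, yates = r$yates_slope,
             c = r$c_statistic, c_lo = r$c_ci[1], c_hi = r$c_ci[2],
             stringsAsFactors = FALSE)
}

pred_rows <- function(model, method, dataset, probs, outcomes) {
  data.frame(model = model, method = method, dataset = dataset,
             prob = probs, outcome = outcomes, stringsAsFactors = FALSE)
}

#' Run the full model-updating experiment
#'
#' Generates (or loads) a cohort, excludes previously diagnosed
#' participants, imputes, splits into training and test sets, then for
#' every requested registry model runs Method 0 as an external validation
#' on the full analysis set and Methods 1-5 fit on the training split and
#' evaluated on both splits; optionally develops a de novo model on the
#' training split. Per-cell failures are caught and recorded so one
#' degenerate fit cannot abort the experiment. Fully deterministic given
#' the configured seeds.
#'
#' @param config An [experiment_config()].
#' @return List of class `report_bundle`: `performance` (one row per model
#'   x method x dataset), `updates` (nested list of `update_result`s),
#'   `predictions` (per-record predicted risks for calibration plots),
#'   `failures`, `seeds` and `config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  registry <- config$registry %||% load_model_registry()
  model_names <- if (identical(config$models, "all")) names(registry)
                 else config$models
  unknown <- setdiff(model_names, names(registry))
  if (length(unknown))
    stop(sprintf("unknown model name(s): %s", paste(unknown, collapse = ", ")))

  cohort <- if (!is.null(config$cohort_csv)) {
    read_cohort_csv(config$cohort_csv)
  } else {
    cfg <- config$cohort
    cfg$seed <- config$seeds$cohort %||% cfg$seed
    generate_cohort(cfg)
  }
  analysis <- simple_impute(exclude_diagnosed(cohort))
  sp <- split_cohort(analysis, fraction = config$split_fraction,
                     seed = config$seeds$split %||% 1L)
  train <- sp$train
  test <- sp$test

  perf <- list()
  preds <- list()
  updates <- list()
  failures <- list()
  bseed <- config$seeds$bootstrap %||% 1L

  add_cell <- function(model_nm, method_nm, fitted_model) {
    for (ds in list(list("train", train), list("test", test))) {
      p <- predict(fitted_model, ds[[2]])
      y <- ds[[2]]$outcome
      perf[[length(perf) + 1]] <<- perf_row(model_nm, method_nm, ds[[1]], p, y)
      preds[[length(preds) + 1]] <<- pred_rows(model_nm, method_nm,
                                               ds[[1]], p, y)
    }
  }

  for (i in seq_along(model_names)) {
    nm <- model_names[i]
    model <- registry[[nm]]
    updates[[nm]] <- list()
    if (0 %in% config$methods) {
      p_full <- predict(model, analysis)
      perf[[length(perf) + 1]] <- perf_row(nm, "0", "full", p_full,
                                           analysis$outcome)
      preds[[length(preds) + 1]] <- pred_rows(nm, "0", "full", p_full,
                                              analysis$outcome)
    }
    runners <- list(
      "1" = function() method1_intercept_adjustment(model, train),
      "2" = function() method2_logistic_calibration(model, train),
      "3" = function() method3_revision(model, train, alpha = config$alpha,
                                        B = config$shrinkage_B,
                                        seed = bseed + 10 * i),
      "4" = function() method4_reestimation(model, train,
                                            B = config$shrinkage_B,
                                            seed = bseed + 10 * i + 1),
      "5" = function() method5_extension(model, train, alpha = config$alpha,
                                         B = config$shrinkage_B,
                                         seed = bseed + 10 * i + 2))
    for (m in intersect(as.character(config$methods), names(runners))) {
      res <- tryCatch(runners[[m]](), error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- list(model = nm, method = m,
                                                 message = conditionMessage(res))
        next
      }
      updates[[nm]][[m]] <- res
      add_cell(nm, m, res$final_model)
    }
  }

  if (isTRUE(config$include_developed)) {
    res <- tryCatch(
      develop_model(train, alpha = config$alpha, B = config$shrinkage_B,
                    seed = bseed + 999),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(model = "developed",
                                               method = "developed",
                                               message = conditionMessage(res))
    } else {
      updates[["developed"]] <- res
      add_cell("developed", "developed", res$final_model)
    }
  }

  structure(list(
    performance = do.call(rbind, perf),
    predictions = do.call(rbind, preds),
    updates = updates, failures = failures,
    seeds = config$seeds, config = config,
    n = list(recruited = nrow(cohort), analysis = nrow(analysis),
             train = nrow(train), test = nrow(test))),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d performance cells (%d failures)\n",
              nrow(x$performance), length(x$failures)))
  cat(sprintf("  n: recruited %d, analysis %d, train %d, test %d\n",
              x$n$recruited, x$n$analysis, x$n$train, x$n$test))
  invisible(x)
}

#' Write the report bundle as CSV tables
#'
#' Emits four CSVs mirroring the study's report layout: the estimated
#' updating parameters (correction factors, calibration intercepts/slopes,
#' deviations, added terms), the full model coefficients per method, and
#' the performance tables for the recalibration methods (0-3) and the
#' refit/extension methods (4, 5, developed). A `provenance.json` with
#' seeds and sample sizes accompanies them.
#'
#' @param bundle A `report_bundle`.
#' @param outdir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
render_tables <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  params <- list()
  coefs <- list()
  for (nm in names(bundle$updates)) {
    ups <- bundle$updates[[nm]]
    if (inherits(ups, "update_result")) ups <- list(developed = ups)
    for (m in names(ups)) {
      u <- ups[[m]]
      params[[length(params) + 1]] <- data.frame(
        model = nm, method = m,
        parameter = "correction_factor",
        term = NA_character_, value = u$correction_factor %||% NA_real_,
        stringsAsFactors = FALSE)
      if (!is.null(u$calibration_intercept)) {
        params[[length(params) + 1]] <- data.frame(
          model = nm, method = m, parameter = "calibration_intercept",
          term = NA_character_, value = u$calibration_intercept,
          stringsAsFactors = FALSE)
        params[[length(params) + 1]] <- data.frame(
          model = nm, method = m, parameter = "calibration_slope",
          term = NA_character_, value = u$calibration_slope,
          stringsAsFactors = FALSE)
      }
      for (set in c("deviations", "added_terms")) {
        v <- u[[set]]
        if (length(v))
          params[[length(params) + 1]] <- data.frame(
            model = nm, method = m, parameter = sub("s$", "", set),
            term = names(v), value = unname(v), stringsAsFactors = FALSE)
      }
      fm <- u$final_model
      coefs[[length(coefs) + 1]] <- data.frame(
        model = nm, method = m,
        term = c("(Intercept)", names(fm$terms)),
        estimate = c(fm$intercept, unname(coef(fm))),
        stringsAsFactors = FALSE)
    }
  }

  write_one <- function(df, file) {
    path <- file.path(outdir, file)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    paths <<- c(paths, path)
  }
  write_one(do.call(rbind, params) %||% data.frame(), "updating_parameters.csv")
  write_one(do.call(rbind, coefs) %||% data.frame(), "model_coefficients.csv")
  pf <- bundle$performance
  write_one(pf[pf$method %in% c("0", "1", "2", "3"), , drop = FALSE],
            "performance_methods_0_3.csv")
  write_one(pf[pf$method %in% c("4", "5", "developed"), , drop = FALSE],
            "performance_methods_4_5.csv")

  prov <- list(seeds = bundle$seeds, n = bundle$n,
               alpha = bundle$config$alpha,
               split_fraction = bundle$config$split_fraction,
               shrinkage_B = bundle$config$shrinkage_B,
               models = names(bundle$updates))
  ppath <- file.path(outdir, "provenance.json")
  jsonlite::write_json(prov, ppath, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, ppath))
}

#' Calibration-curve grid across models and methods
#'
#' One panel per model x method combination, decile calibration points
#' against the 45-degree identity line.
#'
#' @param bundle A `report_bundle` (with retained predictions).
#' @param outdir Output directory; the plot is written as
#'   `calibration_grid.png`.
#' @param n_bins Quantile bins per panel.
#' @param dataset Which evaluation set to plot (`"test"`, `"train"` or
#'   `"full"` for Method 0).
#' @return The ggplot object, invisibly; side effect is the written file.
#' @export
render_calibration_grid <- function(bundle, outdir, n_bins = 10,
                                    dataset = c("test", "train", "full")) {
  if (is.null(bundle$predictions) || !nrow(bundle$predictions))
    stop("bundle carries no predictions")
  dataset <- match.arg(dataset, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pr <- bundle$predictions[bundle$predictions$dataset %in% dataset, ]
  cells <- unique(pr[, c("model", "method", "dataset")])
  curves <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- pr$model == cells$model[i] & pr$method == cells$method[i] &
      pr$dataset == cells$dataset[i]
    cc <- suppressWarnings(
      calibration_curve(pr$prob[sel], pr$outcome[sel], n_bins = n_bins))
    cbind(cells[i, , drop = FALSE], cc, row.names = NULL)
  }))
  gg <- ggplot2::ggplot(curves,
                        ggplot2::aes(x = mean_predicted,
                                     y = observed_proportion)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(method ~ model) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted risk", y = "Observed proportion") +
    ggplot2::theme_bw()
  ggplot2::ggsave(file.path(outdir, "calibration_grid.png"), gg,
                  width = 2 + 2 * length(unique(curves$model)),
                  height = 1.5 + 1.8 * length(unique(curves$method)),
                  dpi = 150, limitsize = FALSE)
  invisible(gg)
}
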