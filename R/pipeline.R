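# Factorial experiment runner: {preprocessors} x {FS, GA, SPA, CARS} x
# {SVR, PCR, PLSR, MLR} x {analytes}, with frozen calibration statistics,
# per-combination caching, and ranked comparison tables.

#' Configuration of a pipeline run
#'
#' @param preprocess character vector of [preprocess_methods()] names.
#' @param selectors subset of `c("FS", "GA", "SPA", "CARS")` (`"FS"` is
#'   the full spectrum, i.e. no selection).
#' @param models subset of `c("SVR", "PCR", "PLSR", "MLR")`.
#' @param analytes subset of `c("starch", "vc", "ssc", "ta")`.
#' @param split_ratio calibration share of samples.
#' @param split_method `"kennard_stone"` or `"random"`.
#' @param split_indices optional fixed split: list with `cal` and `pred`
#'   row indices (overrides the split rule; used e.g. to prove that
#'   prediction rows never influence fitting).
#' @param aggregate_views average the rotational views into per-sample
#'   spectra before modelling (the default); `FALSE` keeps per-view rows.
#' @param preprocess_params named list of parameter lists keyed by
#'   preprocessing method name.
#' @param selector_params named list of argument lists keyed by selector.
#' @param seed master seed for every stochastic stage.
#' @return an object of class `run_config`.
#' @export
pipeline_config <- function(preprocess = "2nd Der",
                            selectors = c("FS", "GA", "SPA", "CARS"),
                            models = c("SVR", "PCR", "PLSR", "MLR"),
                            analytes = c("starch", "vc", "ssc", "ta"),
                            split_ratio = 0.75,
                            split_method = "kennard_stone",
                            split_indices = NULL,
                            aggregate_views = TRUE,
                            preprocess_params = list(),
                            selector_params = list(),
                            seed = 1L) {
  stopifnot(length(preprocess) >= 1, length(selectors) >= 1,
            length(models) >= 1, length(analytes) >= 1)
  bad <- setdiff(preprocess, preprocess_methods())
  if (length(bad))
    stop_config("unknown preprocessing method: ",
                paste(bad, collapse = ", "))
  selectors <- match.arg(selectors, c("FS", "GA", "SPA", "CARS"),
                         several.ok = TRUE)
  models <- match.arg(models, c("SVR", "PCR", "PLSR", "MLR"),
                      several.ok = TRUE)
  analytes <- match.arg(analytes, c("starch", "vc", "ssc", "ta"),
                        several.ok = TRUE)
  structure(list(preprocess = preprocess, selectors = selectors,
                 models = models, analytes = analytes,
                 split_ratio = split_ratio, split_method = split_method,
                 split_indices = split_indices,
                 aggregate_views = aggregate_views,
                 preprocess_params = preprocess_params,
                 selector_params = selector_params,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Preprocess calibration rows, freeze any fitted statistics, and apply
# the frozen transform to prediction rows. Only MSC carries statistics
# (its reference spectrum); every other method is per-row.
preprocess_cal_pred <- function(Xcal, Xpred, method, params) {
  cal <- apply_pipeline(Xcal, method, params)
  if (method == "MSC") {
    ref <- attr(cal, "msc_reference")
    pred <- apply_pipeline(Xpred, method,
                           modifyList(params, list(reference = ref)))
  } else {
    pred <- apply_pipeline(Xpred, method, params)
  }
  list(cal = cal, pred = pred)
}

run_selector <- function(selector, X, y, params, seed) {
  switch(selector,
         FS = selection_result("FS", seq_len(ncol(X$values)),
                               ncol(X$values),
                               wavelengths = X$wavelengths),
         GA = do.call(ga_select, c(list(X, y), params,
                                   if (is.null(params$seed))
                                     list(seed = seed))),
         SPA = do.call(spa_select, c(list(X, y), params)),
         CARS = do.call(cars_select, c(list(X, y), params,
                                       if (is.null(params$seed))
                                         list(seed = seed))))
}

#' Run the factorial calibration experiment
#'
#' Executes, for every configured combination of preprocessing method,
#' wavelength selector, model and analyte: split into calibration and
#' prediction sets (once, on the raw spectra, so every combination sees
#' the same partition), preprocessing with calibration-set statistics
#' frozen and reused on prediction rows, wavelength selection and
#' hyperparameter cross-validation on the calibration set only, model
#' fitting, and evaluation. Per-stage results are cached across the
#' factorial grid. A combination that fails (e.g. MLR on the full
#' spectrum, where features outnumber samples) is recorded with a `"/"`
#' marker and the run continues.
#'
#' @param spectra a [spectra_matrix()] of per-view or per-sample
#'   spectra.
#' @param reference a `reference_table` (or data.frame with `sample_id`
#'   and analyte columns) matching the spectra's samples.
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_result`: list with `table` (the
#'   comparison data.frame: analyte, model, extraction, n_wavelengths,
#'   rc2, rmsec, rp2, rmsep, note, best), `selections`, `reports`,
#'   `significance` (for MLR rows), `split`, and `config`.
#' @export
run_pipeline <- function(spectra, reference, config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  sp <- if (config$aggregate_views) aggregate_views(spectra) else spectra
  ref <- as.data.frame(reference)
  m <- match(sp$sample_id, ref$sample_id)
  if (anyNA(m))
    stop_config("spectra contain sample_ids missing from the reference ",
                "table")
  ref <- ref[m, , drop = FALSE]

  n <- nrow(sp$values)
  if (is.null(config$split_indices)) {
    s0 <- split_calibration_prediction(sp$values, ref[[config$analytes[1]]],
                                       ratio = config$split_ratio,
                                       method = config$split_method,
                                       seed = config$seed)
    cal_idx <- s0$cal$idx
    pred_idx <- s0$pred$idx
  } else {
    cal_idx <- config$split_indices$cal
    pred_idx <- config$split_indices$pred
  }

  sub_rows <- function(i) spectra_matrix(sp$values[i, , drop = FALSE],
                                         sp$wavelengths,
                                         sample_id = sp$sample_id[i])
  Xcal_raw <- sub_rows(cal_idx)
  Xpred_raw <- sub_rows(pred_idx)

  prep_cache <- list()
  sel_cache <- list()
  selections <- list()
  reports <- list()
  signif <- list()
  rows <- list()

  for (pm in config$preprocess) {
    if (is.null(prep_cache[[pm]]))
      prep_cache[[pm]] <- preprocess_cal_pred(
        Xcal_raw, Xpred_raw, pm,
        config$preprocess_params[[pm]] %||% list())
    pp <- prep_cache[[pm]]
    for (an in config$analytes) {
      ycal <- ref[[an]][cal_idx]
      ypred <- ref[[an]][pred_idx]
      for (sel in config$selectors) {
        skey <- paste(pm, an, sel, sep = "|")
        if (is.null(sel_cache[[skey]])) {
          spar <- config$selector_params[[sel]] %||% list()
          # every configured model must be able to consume the subset;
          # MLR needs more samples than bands, the usual reason for
          # selecting wavelengths at all
          if (sel == "CARS" && is.null(spar$max_bands) &&
              "MLR" %in% config$models)
            spar$max_bands <- length(cal_idx) - 2L
          sel_cache[[skey]] <- tryCatch(
            run_selector(sel, pp$cal, ycal, spar, config$seed),
            error = function(e) e)
        }
        selres <- sel_cache[[skey]]
        if (inherits(selres, "error")) {
          for (mod in config$models)
            rows[[length(rows) + 1L]] <- data.frame(
              analyte = an, model = mod, extraction = sel,
              n_wavelengths = NA_integer_, rc2 = NA_real_,
              rmsec = NA_real_, rp2 = NA_real_, rmsep = NA_real_,
              note = conditionMessage(selres))
          next
        }
        selections[[skey]] <- selres
        bands <- selres$indices
        Xc <- pp$cal$values[, bands, drop = FALSE]
        Xp <- pp$pred$values[, bands, drop = FALSE]
        for (mod in config$models) {
          note <- ""
          rep_i <- tryCatch({
            fit <- fit_model(Xc, ycal, mod, seed = config$seed)
            ev <- evaluate(fit, list(X = Xc, y = ycal),
                           list(X = Xp, y = ypred),
                           label = list(preprocess = pm, selector = sel,
                                        model = mod, analyte = an))
            if (mod == "MLR") {
              sk <- paste(skey, "MLR", sep = "|")
              signif[[sk]] <- tryCatch(
                mlr_significance(Xc, ycal,
                                 wavelengths = pp$cal$wavelengths[bands],
                                 analyte = an),
                error = function(e) e)
            }
            ev
          }, error = function(e) e)
          if (inherits(rep_i, "error")) {
            note <- if (mod == "MLR" && sel == "FS") "/"
                    else conditionMessage(rep_i)
            rows[[length(rows) + 1L]] <- data.frame(
              analyte = an, model = mod, extraction = sel,
              n_wavelengths = selres$n_selected, rc2 = NA_real_,
              rmsec = NA_real_, rp2 = NA_real_, rmsep = NA_real_,
              note = note)
          } else {
            key <- paste(pm, an, sel, mod, sep = "|")
            reports[[key]] <- rep_i
            rows[[length(rows) + 1L]] <- data.frame(
              analyte = an, model = mod, extraction = sel,
              preprocess = pm,
              n_wavelengths = selres$n_selected,
              rc2 = rep_i$rc2, rmsec = rep_i$rmsec,
              rp2 = rep_i$rp2, rmsep = rep_i$rmsep, note = note)
          }
        }
      }
    }
  }

  tab <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$preprocess)) r$preprocess <- NA_character_
    r[, c("analyte", "model", "extraction", "preprocess",
          "n_wavelengths", "rc2", "rmsec", "rp2", "rmsep", "note")]
  }))
  rownames(tab) <- NULL
  tab$best <- FALSE
  for (an in unique(tab$analyte)) {
    i <- which(tab$analyte == an & !is.na(tab$rp2))
    if (length(i)) {
      ord <- i[order(-tab$rp2[i], tab$rmsep[i])]
      tab$best[ord[1]] <- TRUE
    }
  }

  structure(list(table = tab, selections = selections, reports = reports,
                 significance = signif,
                 split = list(cal = cal_idx, pred = pred_idx),
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d combinations (%d cal / %d pred samples)\n",
              nrow(x$table), length(x$split$cal), length(x$split$pred)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Rank preprocessing methods by prediction performance
#'
#' Orders comparison-table rows by prediction R-squared (descending),
#' breaking ties by prediction RMSE (ascending) — the criterion used to
#' call one preprocessing method optimal.
#'
#' @param table a comparison table (`pipeline_result$table` or a
#'   compatible data.frame with `rp2` and `rmsep` columns).
#' @return the table rows, reordered; rows with missing `rp2` sink to
#'   the bottom.
#' @export
rank_preprocessing <- function(table) {
  if (inherits(table, "pipeline_result")) table <- table$table
  ord <- order(-table$rp2, table$rmsep, na.last = TRUE)
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare all preprocessing methods on one analyte
#'
#' Convenience wrapper for the preprocessing-comparison stage: every
#' registry method, full spectrum, one model (PLSR by default), one
#' analyte (starch by default).
#'
#' @param spectra,reference as in [run_pipeline()].
#' @param analyte analyte compared on.
#' @param model model used.
#' @param seed master seed.
#' @param ... further arguments to [pipeline_config()].
#' @return a `pipeline_result`.
#' @export
run_preprocessing_comparison <- function(spectra, reference,
                                         analyte = "starch",
                                         model = "PLSR", seed = 1L, ...) {
  run_pipeline(spectra, reference,
               pipeline_config(preprocess = preprocess_methods(),
                               selectors = "FS", models = model,
                               analytes = analyte, seed = seed, ...))
}
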