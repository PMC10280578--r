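#' Pipeline run configuration
#'
#' One object describing a full analysis: input source, pretreatment,
#' wavelength selector, classifier, ensemble scale, split and repeat
#' protocol.
#'
#' @param source either a [synth_config()] (synthetic input) or the path
#'   to a manifest accepted by [read_spectra_table()].
#' @param preprocess pretreatment method: `"none"`, `"msc"`, `"snv"` or
#'   `"sg1"`.
#' @param selector wavelength selector: `"none"`, `"cars"` or `"iriv"`.
#' @param model classifier: `"lda"`, `"knn"`, `"svm"`, `"dt"` or
#'   `"rsel"` (random-subspace ensemble over `base`).
#' @param rsel_n,rsel_d ensemble scale (members, subspace dimension);
#'   `rsel_d` is clipped to the number of selected bands.
#' @param base a [base_classifier_spec()] used directly (single-model
#'   runs) or as the ensemble's base learner.
#' @param n_train Kennard-Stone training-set size (default 270 of 360).
#' @param stratified run the Kennard-Stone split per class.
#' @param repeats model repeats averaged in the report (default 10).
#' @param seed base seed for the selector and the repeated models.
#' @param cars,iriv selector configurations; their `seed` is overridden
#'   by `seed`.
#' @param out_dir optional directory for `report.json` / `bands.json`.
#' @return list of class `run_config`.
#' @export
run_config <- function(source = synth_config(),
                       preprocess = c("msc", "none", "snv", "sg1"),
                       selector = c("none", "cars", "iriv"),
                       model = c("rsel", "lda", "knn", "svm", "dt"),
                       rsel_n = 25, rsel_d = 63,
                       base = base_classifier_spec("lda"), n_train = 270,
                       stratified = FALSE, repeats = 10, seed = 1,
                       cars = cars_config(), iriv = iriv_config(),
                       out_dir = NULL) {
  structure(list(source = source, preprocess = match.arg(preprocess),
                 selector = match.arg(selector), model = match.arg(model),
                 rsel_n = rsel_n, rsel_d = rsel_d, base = base,
                 n_train = n_train, stratified = stratified,
                 repeats = repeats, seed = seed, cars = cars, iriv = iriv,
                 out_dir = out_dir),
            class = "run_config")
}

load_input <- function(source) {
  if (inherits(source, "synth_config")) return(sample_dataset(source)$table)
  if (inherits(source, "spectra_table")) return(source)
  if (is.character(source)) return(read_spectra_table(source))
  stop_hyperseed("hyperseed_config_error",
                 "unrecognised input source of class '%s'",
                 paste(class(source), collapse = "/"))
}

# Preprocess -> Kennard-Stone split -> refit of the pretreatment on the
# training rows only. The split is computed on provisionally
# preprocessed spectra (reference fitted on all rows) so the partition
# sees the geometry the model will see; the pretreatment applied to the
# final matrices is then refitted on the training rows alone, so no
# prediction-set information enters the frozen reference.
split_and_preprocess <- function(table, method, n_train,
                                 stratified = FALSE) {
  prov <- preprocess_fit(table$X, method)
  Xp <- preprocess_apply(prov, table$X)
  part <- if (stratified) ks_split_stratified(Xp, table$labels, n_train)
          else ks_split(Xp, n_train)
  tr <- part$train_idx
  te <- part$test_idx
  prep <- preprocess_fit(table$X[tr, , drop = FALSE], method)
  list(X_train = preprocess_apply(prep, table$X[tr, , drop = FALSE]),
       X_test = preprocess_apply(prep, table$X[te, , drop = FALSE]),
       y_train = droplevels(table$labels[tr]),
       y_test = droplevels(table$labels[te]),
       partition = part, prep = prep)
}

select_bands <- function(X_train, y_train, selector, config) {
  switch(selector,
         none = NULL,
         cars = {
           cfg <- config$cars
           cfg$seed <- config$seed
           cars_select(X_train, y_train, cfg)
         },
         iriv = {
           cfg <- config$iriv
           cfg$seed <- config$seed
           iriv_select(X_train, y_train, cfg)
         })
}

#' Run the full identification pipeline
#'
#' Ingest (or simulate) seed spectra, pretreat, split by Kennard-Stone,
#' select wavelengths on the training set, train the classifier over
#' `repeats` reseeded runs, and evaluate on the prediction set. Fitting
#' is train-only throughout: the pretreatment reference and the selected
#' bands are learned from the training rows and frozen before the
#' prediction rows are touched.
#'
#' @param config a [run_config()].
#' @return an object of class `pipeline_result`: `report` (an
#'   [repeat_and_average()] eval report on the prediction set),
#'   `train_report` (same protocol on the training set), `bands`
#'   (selected `variable_subset` or `NULL`), `partition`, and `config`.
#'   When `config$out_dir` is set, `report.json` and `bands.json` are
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  table <- load_input(config$source)
  prep <- split_and_preprocess(table, config$preprocess, config$n_train,
                               config$stratified)
  bands <- select_bands(prep$X_train, prep$y_train, config$selector,
                        config)
  idx <- if (is.null(bands)) seq_len(ncol(prep$X_train)) else bands$indices
  Xtr <- prep$X_train[, idx, drop = FALSE]
  Xte <- prep$X_test[, idx, drop = FALSE]
  classes <- levels(prep$y_train)
  fit_once <- function(seed) {
    if (config$model == "rsel") {
      d <- min(config$rsel_d, ncol(Xtr))
      ens <- train_rsel(Xtr, prep$y_train,
                        rsel_config(config$rsel_n, d, base = config$base,
                                    seed = seed))
      list(test = predict_rsel(ens, Xte)$labels,
           train = predict_rsel(ens, Xtr)$labels)
    } else {
      spec <- config$base
      spec$kind <- config$model
      clf <- train_base(spec, Xtr, prep$y_train)
      list(test = classes[row_argmax(predict_base(clf, Xte))],
           train = classes[row_argmax(predict_base(clf, Xtr))])
    }
  }
  report <- repeat_and_average(function(seed) {
    list(y_true = prep$y_test, y_pred = fit_once(seed)$test)
  }, n_repeats = config$repeats, base_seed = config$seed,
  classes = classes)
  train_report <- repeat_and_average(function(seed) {
    list(y_true = prep$y_train, y_pred = fit_once(seed)$train)
  }, n_repeats = config$repeats, base_seed = config$seed,
  classes = classes)
  result <- structure(list(report = report, train_report = train_report,
                           bands = bands, partition = prep$partition,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %s + %s + %s\n", x$config$preprocess,
              x$config$selector, x$config$model))
  if (!is.null(x$bands))
    cat(sprintf("  %d selected band(s)\n", length(x$bands$indices)))
  cat(sprintf("  prediction set: precision %.4f, kappa %.4f\n",
              x$report$precision, x$report$kappa))
  cat(sprintf("  training set:   precision %.4f, kappa %.4f\n",
              x$train_report$precision, x$train_report$kappa))
  invisible(x)
}

# Serialisable echo of a run configuration (drops the nested objects'
# classes, keeps every parameter).
config_echo <- function(config) {
  src <- if (inherits(config$source, "synth_config"))
    c(list(type = "synth"), unclass(config$source))
  else list(type = "tables", path = as.character(config$source))
  list(source = src, preprocess = config$preprocess,
       selector = config$selector, model = config$model,
       rsel_n = config$rsel_n, rsel_d = config$rsel_d,
       base = unclass(config$base), n_train = config$n_train,
       stratified = config$stratified, repeats = config$repeats,
       seed = config$seed)
}

write_pipeline_artifacts <- function(result) {
  dir.create(result$config$out_dir, showWarnings = FALSE,
             recursive = TRUE)
  report <- list(
    config = config_echo(result$config),
    precision = result$report$precision, kappa = result$report$kappa,
    kappa_pooled = result$report$kappa_pooled,
    per_repeat = result$report$per_repeat,
    confusion = as.data.frame.matrix(result$report$confusion),
    train_precision = result$train_report$precision,
    train_kappa = result$train_report$kappa,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(report,
                       file.path(result$config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$bands))
    jsonlite::write_json(
      list(method = result$bands$method,
           indices = result$bands$indices,
           rmsecv = result$bands$rmsecv,
           trace = result$bands$trace),
      file.path(result$config$out_dir, "bands.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Ensemble-scale tables for every selector
#'
#' Reproduces the ensemble-scale sweep: for each requested selector the
#' data are pretreated, split, reduced to the selected bands, and a
#' member-count x subspace-dimension grid of mean prediction precisions
#' is computed with [grid_search_rsel()]. The conventional layout is six
#' member counts (15-40) against dimensions 20-100 (step 10) on the full
#' bands and 20-65 (step 5) after selection.
#'
#' @param config a [run_config()]; its `preprocess`, `n_train`, `seed`,
#'   `repeats` and selector settings are used.
#' @param selectors selectors to sweep (default all three).
#' @param n_list member counts (default `c(15, 20, 25, 30, 35, 40)`).
#' @param d_list_full,d_list_selected dimension grids for the full-band
#'   and post-selection sweeps; entries above the available band count
#'   are dropped.
#' @param weight_rule member weighting passed to [grid_search_rsel()].
#' @param out_dir optional directory; one `table_<selector>.csv` each.
#' @return named list of precision matrices.
#' @export
reproduce_tables <- function(config,
                             selectors = c("none", "cars", "iriv"),
                             n_list = c(15, 20, 25, 30, 35, 40),
                             d_list_full = seq(20, 100, 10),
                             d_list_selected = seq(20, 65, 5),
                             weight_rule = "cv_accuracy",
                             out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  table <- load_input(config$source)
  prep <- split_and_preprocess(table, config$preprocess, config$n_train,
                               config$stratified)
  out <- list()
  for (sel in selectors) {
    bands <- select_bands(prep$X_train, prep$y_train, sel, config)
    idx <- if (is.null(bands)) seq_len(ncol(prep$X_train))
           else bands$indices
    d_list <- if (sel == "none") d_list_full else d_list_selected
    d_list <- d_list[d_list <= length(idx)]
    grid <- grid_search_rsel(prep$X_train[, idx, drop = FALSE],
                             prep$y_train,
                             prep$X_test[, idx, drop = FALSE],
                             prep$y_test, n_list, d_list,
                             repeats = config$repeats,
                             base = config$base,
                             weight_rule = weight_rule,
                             seed = config$seed)
    out[[sel]] <- grid
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(grid,
                       file.path(out_dir,
                                 sprintf("table_%s.csv", sel)))
    }
  }
  out
}
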