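#' Random-subspace ensemble configuration
#'
#' @param n_learners number of ensemble members N.
#' @param subspace_dim feature-subspace dimension d drawn per member.
#' @param base a [base_classifier_spec()] (default LDA).
#' @param weight_rule `"cv_accuracy"` (default): weight each member by
#'   its stratified 5-fold cross-validated training accuracy,
#'   renormalised; or `"uniform"`.
#' @param accept_threshold members whose cross-validated accuracy falls
#'   below this are dropped (default `1/6`, chance level for six
#'   classes). Ignored under uniform weighting.
#' @param weight_folds folds of the weighting cross-validation.
#' @param seed integer RNG seed; fixes the member subspaces and weights.
#' @return list of class `rsel_config`.
#' @export
rsel_config <- function(n_learners, subspace_dim,
                        base = base_classifier_spec("lda"),
                        weight_rule = c("cv_accuracy", "uniform"),
                        accept_threshold = 1 / 6, weight_folds = 5,
                        seed = 1) {
  weight_rule <- match.arg(weight_rule)
  stopifnot(n_learners >= 1, subspace_dim >= 1)
  structure(list(n_learners = n_learners, subspace_dim = subspace_dim,
                 base = base, weight_rule = weight_rule,
                 accept_threshold = accept_threshold,
                 weight_folds = weight_folds, seed = seed),
            class = "rsel_config")
}

#' Train a random-subspace ensemble
#'
#' Each of the N members draws `subspace_dim` feature indices uniformly
#' without replacement (a fresh draw per member; members may overlap),
#' trains the base classifier on all training rows restricted to those
#' features, and receives a weight from `weight_rule`. Members below the
#' acceptance threshold are dropped; the remaining weights are
#' renormalised to sum to one. Predictions combine member class scores by
#' the weighted average.
#'
#' @param X training matrix (samples x bands) or a [spectra_table()].
#' @param y class labels (taken from the table when `X` is one).
#' @param config an [rsel_config()].
#' @return an object of class `trained_ensemble`: `members` (list of
#'   `feature_idx`, `clf`, `weight`), `classes`, `n_bands`, `config`.
#' @export
train_rsel <- function(X, y = NULL, config) {
  if (inherits(X, "spectra_table")) {
    y <- X$labels
    X <- X$X
  }
  stopifnot(inherits(config, "rsel_config"))
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  d <- config$subspace_dim
  if (d > ncol(X))
    stop_hyperseed("hyperseed_config_error",
                   "subspace_dim %d exceeds the %d available band(s)", d,
                   ncol(X))
  with_seed(config$seed, {
    members <- vector("list", config$n_learners)
    for (m in seq_len(config$n_learners)) {
      idx <- sort(sample(ncol(X), d))
      clf <- train_base(config$base, X[, idx, drop = FALSE], y)
      w <- if (config$weight_rule == "uniform") 1 else
        cv_accuracy(config$base, X[, idx, drop = FALSE], y,
                    config$weight_folds)
      members[[m]] <- list(feature_idx = idx, clf = clf, weight = w)
    }
    if (config$weight_rule == "cv_accuracy") {
      keep <- vapply(members, function(m) m$weight, 1) >=
        config$accept_threshold
      members <- members[keep]
    }
    if (length(members) == 0)
      stop_hyperseed("hyperseed_ensemble_empty",
                     "every member fell below the acceptance threshold %.3f",
                     config$accept_threshold)
    tot <- sum(vapply(members, function(m) m$weight, 1))
    for (m in seq_along(members))
      members[[m]]$weight <- members[[m]]$weight / tot
    structure(list(members = members, classes = levels(y),
                   n_bands = ncol(X), config = config),
              class = "trained_ensemble")
  })
}

# Stratified k-fold cross-validated accuracy of one base classifier.
cv_accuracy <- function(spec, X, y, folds = 5) {
  y <- droplevels(as.factor(y))
  foldid <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(min(folds, length(idx))),
                                  length(idx)))
  }
  hits <- 0L
  for (f in unique(foldid)) {
    tr <- foldid != f
    if (nlevels(droplevels(y[tr])) < 2 || any(table(y[tr]) < 2)) next
    clf <- train_base(spec, X[tr, , drop = FALSE], y[tr])
    S <- predict_base(clf, X[!tr, , drop = FALSE])
    pred <- clf$classes[row_argmax(S)]
    hits <- hits + sum(pred == as.character(y[!tr]))
  }
  hits / length(y)
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat(sprintf("trained_ensemble: %d member(s) (%s, d = %d) over %d class(es)\n",
              length(x$members), x$config$base$kind,
              x$config$subspace_dim, length(x$classes)))
  invisible(x)
}

#' Predict from a random-subspace ensemble
#'
#' Weighted average of the member class-score matrices; the label is the
#' argmax, with ties resolved to the lowest class index.
#'
#' @param ensemble a `trained_ensemble`.
#' @param X matrix with the full band dimension the members index into,
#'   or a [spectra_table()].
#' @return list with `labels` (factor) and `scores` (samples x classes,
#'   rows summing to one).
#' @export
predict_rsel <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  if (inherits(X, "spectra_table")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != ensemble$n_bands)
    stop_hyperseed("hyperseed_shape_error",
                   "ensemble was trained on %d band(s); input has %d",
                   ensemble$n_bands, ncol(X))
  scores <- matrix(0, nrow(X), length(ensemble$classes),
                   dimnames = list(NULL, ensemble$classes))
  for (m in ensemble$members)
    scores <- scores +
      m$weight * predict_base(m$clf, X[, m$feature_idx, drop = FALSE])
  labels <- factor(ensemble$classes[row_argmax(scores)],
                   levels = ensemble$classes)
  list(labels = labels, scores = scores)
}

#' Grid search over ensemble scale
#'
#' Mean prediction-set precision for every combination of member count
#' and subspace dimension, averaged over `repeats` reseeded ensembles —
#' the table layout used to pick the operating point of the ensemble.
#'
#' @param X_train,y_train,X_test,y_test training and prediction data on
#'   a common band dimension.
#' @param n_list member counts to try.
#' @param d_list subspace dimensions to try (each <= band count).
#' @param repeats ensembles averaged per cell (default 10).
#' @param base,weight_rule passed to [rsel_config()].
#' @param seed base seed; repeat r of any cell uses `seed + r - 1`.
#' @return matrix of mean precisions, rows = `n_list`, cols = `d_list`.
#' @export
grid_search_rsel <- function(X_train, y_train, X_test, y_test, n_list,
                             d_list, repeats = 10,
                             base = base_classifier_spec("lda"),
                             weight_rule = "cv_accuracy", seed = 1) {
  stopifnot(all(d_list <= ncol(as.matrix(X_train))))
  grid <- matrix(NA_real_, length(n_list), length(d_list),
                 dimnames = list(n_learners = n_list,
                                 subspace_dim = d_list))
  for (i in seq_along(n_list)) for (j in seq_along(d_list)) {
    acc <- vapply(seq_len(repeats), function(r) {
      cfg <- rsel_config(n_list[i], d_list[j], base = base,
                         weight_rule = weight_rule, seed = seed + r - 1)
      ens <- train_rsel(X_train, y_train, cfg)
      pred <- predict_rsel(ens, X_test)
      mean(as.character(pred$labels) == as.character(y_test))
    }, numeric(1))
    grid[i, j] <- mean(acc)
  }
  grid
}
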