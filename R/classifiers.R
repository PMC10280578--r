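#' Base classifier specification
#'
#' Hyperparameter bundle for the four base classifiers, with the defaults
#' used throughout: KNN with 20 neighbours under the Minkowski (order 2)
#' metric and inverse-distance vote weighting; a Gini decision tree
#' capped at 20 splits; a linear-kernel SVM with box constraint 3
#' (one-vs-one, vote-normalised scores); and LDA.
#'
#' @param kind one of `"lda"`, `"knn"`, `"svm"`, `"dt"`.
#' @param knn_k neighbours (default 20).
#' @param knn_order Minkowski order (default 2, Euclidean).
#' @param knn_weight `"inverse"` (default), `"equal"` or
#'   `"inverse_squared"` neighbour weighting.
#' @param dt_max_splits cap on decision-tree splits (default 20).
#' @param svm_cost SVM box constraint (default 3).
#' @return list of class `base_classifier_spec`.
#' @export
base_classifier_spec <- function(kind = c("lda", "knn", "svm", "dt"),
                                 knn_k = 20, knn_order = 2,
                                 knn_weight = c("inverse", "equal",
                                                "inverse_squared"),
                                 dt_max_splits = 20, svm_cost = 3) {
  kind <- match.arg(kind)
  knn_weight <- match.arg(knn_weight)
  stopifnot(knn_k >= 1, knn_order > 0, dt_max_splits >= 1, svm_cost > 0)
  structure(list(kind = kind, knn_k = knn_k, knn_order = knn_order,
                 knn_weight = knn_weight, dt_max_splits = dt_max_splits,
                 svm_cost = svm_cost),
            class = "base_classifier_spec")
}

#' Train a base classifier
#'
#' Fits the classifier named by `spec` and wraps it behind a uniform
#' interface: [predict_base()] returns per-class scores in `[0, 1]`
#' summing to one per sample, whatever the backend.
#'
#' @param spec a [base_classifier_spec()].
#' @param X numeric training matrix.
#' @param y class labels (factor or coercible), >= 2 classes present.
#' @return an object of class `base_classifier`.
#' @export
train_base <- function(spec, X, y) {
  stopifnot(inherits(spec, "base_classifier_spec"))
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop_hyperseed("hyperseed_degenerate_class",
                   "training data holds a single class")
  fit <- switch(spec$kind,
    lda = {
      if (any(table(y) < 2))
        stop_hyperseed("hyperseed_degenerate_class",
                       "LDA needs >= 2 training samples per class")
      MASS::lda(X, grouping = y)
    },
    knn = list(X = X, y = y),
    svm = e1071::svm(X, y, kernel = "linear", cost = spec$svm_cost,
                     scale = FALSE),
    dt = {
      df <- data.frame(.y = y, X)
      tree <- rpart::rpart(.y ~ ., df, method = "class",
                           control = rpart::rpart.control(
                             cp = 0, xval = 0, minsplit = 4,
                             minbucket = 2))
      # prune back to the spec's split budget using the complexity path
      cp_tab <- tree$cptable
      ok <- cp_tab[, "nsplit"] <= spec$dt_max_splits
      cp_star <- cp_tab[max(which(ok)), "CP"]
      rpart::prune(tree, cp = cp_star)
    })
  structure(list(spec = spec, fit = fit, classes = levels(y)),
            class = "base_classifier")
}

#' Per-class scores of a base classifier
#'
#' @param clf a `base_classifier` from [train_base()].
#' @param X numeric matrix with the feature dimension the classifier was
#'   trained on.
#' @return samples x classes matrix of scores; rows sum to one.
#' @export
predict_base <- function(clf, X) {
  stopifnot(inherits(clf, "base_classifier"))
  X <- as.matrix(X)
  S <- switch(clf$spec$kind,
    lda = predict(clf$fit, X)$posterior,
    knn = knn_scores(clf$fit$X, clf$fit$y, X, clf$spec),
    svm = svm_vote_scores(clf$fit, X, clf$classes),
    dt = predict(clf$fit, data.frame(X), type = "prob"))
  S <- S[, clf$classes, drop = FALSE]
  S <- S / rowSums(S)
  dimnames(S) <- list(NULL, clf$classes)
  S
}

#' @export
print.base_classifier <- function(x, ...) {
  cat(sprintf("base_classifier: %s over %d class(es)\n", x$spec$kind,
              length(x$classes)))
  invisible(x)
}

# Weighted k-nearest-neighbour class scores under the Minkowski metric.
knn_scores <- function(Xtr, ytr, Xte, spec) {
  k <- min(spec$knn_k, nrow(Xtr))
  ord <- spec$knn_order
  S <- matrix(0, nrow(Xte), nlevels(ytr),
              dimnames = list(NULL, levels(ytr)))
  for (i in seq_len(nrow(Xte))) {
    d <- (rowSums(abs(Xtr - matrix(Xte[i, ], nrow(Xtr), ncol(Xtr),
                                   byrow = TRUE))^ord))^(1 / ord)
    nn <- order(d)[seq_len(k)]
    w <- switch(spec$knn_weight,
                equal = rep(1, k),
                inverse = 1 / pmax(d[nn], 1e-12),
                inverse_squared = 1 / pmax(d[nn], 1e-12)^2)
    tw <- tapply(w, ytr[nn], sum)
    S[i, names(tw)[!is.na(tw)]] <- tw[!is.na(tw)]
  }
  S / rowSums(S)
}

# One-vs-one vote counts from the SVM's pairwise decision values,
# normalised to sum to one; deterministic (no Platt scaling).
svm_vote_scores <- function(fit, X, classes) {
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  votes <- matrix(0, nrow(X), length(classes),
                  dimnames = list(NULL, classes))
  for (j in seq_len(ncol(dv))) {
    pair <- strsplit(colnames(dv)[j], "/")[[1]]
    win <- ifelse(dv[, j] > 0, pair[1], pair[2])
    votes[cbind(seq_len(nrow(X)), match(win, classes))] <-
      votes[cbind(seq_len(nrow(X)), match(win, classes))] + 1
  }
  # an all-zero row cannot occur (every pair casts one vote)
  votes / rowSums(votes)
}
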