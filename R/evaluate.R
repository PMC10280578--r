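#' Confusion matrix with a fixed class order
#'
#' @param y_true,y_pred equal-length label vectors; every label must be
#'   one of `classes`.
#' @param classes class ordering of the rows and columns; defaults to the
#'   sorted union of the observed labels.
#' @return classes x classes count matrix, rows = truth.
#' @export
confusion <- function(y_true, y_pred,
                      classes = sort(unique(c(as.character(y_true),
                                              as.character(y_pred))))) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown))
    stop_hyperseed("hyperseed_label_error", "unknown label(s): %s",
                   paste(unknown, collapse = ", "))
  table(factor(y_true, classes), factor(y_pred, classes),
        dnn = c("truth", "predicted"))
}

#' Overall precision (accuracy) of a confusion matrix
#'
#' @param cm square count matrix, rows = truth.
#' @return fraction of correctly classified samples.
#' @export
precision_overall <- function(cm) sum(diag(as.matrix(cm))) / sum(cm)

#' Macro-averaged per-class precision
#'
#' Mean over classes of `TP / predicted-positive`; classes never
#' predicted are skipped.
#'
#' @inheritParams precision_overall
#' @export
precision_macro <- function(cm) {
  cm <- as.matrix(cm)
  pp <- colSums(cm)
  mean((diag(cm) / pp)[pp > 0])
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed agreement (trace fraction) and `p_e` the agreement expected
#' from the marginals.
#'
#' @inheritParams precision_overall
#' @return kappa in `[-1, 1]`; when the marginals concentrate all mass so
#'   that `p_e = 1`, kappa is returned as 0 with a warning.
#' @export
kappa_statistic <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  stopifnot(total > 0)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < .Machine$double.eps) {
    warning("expected agreement is 1; kappa undefined, returning 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Repeat a stochastic pipeline and average its scores
#'
#' Runs `pipeline_fn(seed)` for `n_repeats` consecutive seeds and
#' aggregates: per-repeat precision and kappa, their means, and both the
#' pooled confusion matrix (sum over repeats) and the kappa of that
#' pooled matrix.
#'
#' @param pipeline_fn function of one integer seed returning a list (or
#'   2-column structure) with `y_true` and `y_pred`.
#' @param n_repeats number of repeats (default 10).
#' @param base_seed first seed; repeat r uses `base_seed + r - 1`.
#' @param classes optional fixed class ordering.
#' @return an object of class `eval_report`: `confusion` (pooled),
#'   `precision`, `kappa` (means over repeats), `kappa_pooled`,
#'   `per_repeat` (data frame with seed, precision, kappa), `n_repeats`.
#' @export
repeat_and_average <- function(pipeline_fn, n_repeats = 10, base_seed = 1,
                               classes = NULL) {
  n_repeats <- as.integer(n_repeats)
  per <- vector("list", n_repeats)
  pooled <- NULL
  for (r in seq_len(n_repeats)) {
    seed <- as.integer(base_seed) + r - 1L
    res <- tryCatch(pipeline_fn(seed), error = function(e)
      stop_hyperseed("hyperseed_repeat_failed",
                     "repeat with seed %d failed: %s", seed,
                     conditionMessage(e)))
    cls <- classes %||%
      sort(unique(c(as.character(res$y_true), as.character(res$y_pred))))
    cm <- confusion(res$y_true, res$y_pred, cls)
    pooled <- if (is.null(pooled)) unclass(cm) else pooled + unclass(cm)
    per[[r]] <- data.frame(seed = seed,
                           precision = precision_overall(cm),
                           kappa = kappa_statistic(cm))
  }
  per <- do.call(rbind, per)
  structure(list(confusion = pooled, precision = mean(per$precision),
                 kappa = mean(per$kappa),
                 kappa_pooled = kappa_statistic(pooled),
                 per_repeat = per, n_repeats = n_repeats),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d repeat(s)\n  mean precision %.4f, mean kappa %.4f (pooled kappa %.4f)\n",
              x$n_repeats, x$precision, x$kappa, x$kappa_pooled))
  cat("pooled confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
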