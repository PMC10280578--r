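#' Fit a multi-response PLS (SIMPLS) model
#'
#' Partial least squares regression of a response matrix on a spectral
#' matrix using the SIMPLS algorithm. Classification problems are handled
#' as PLS2 on a one-indicator-per-class response matrix (see
#' [pls_rmsecv()]).
#'
#' @param X numeric matrix, samples x bands.
#' @param Y numeric response matrix (or a factor, which is expanded to a
#'   class-indicator matrix).
#' @param ncomp number of latent variables; clipped to
#'   `min(nrow(X) - 1, ncol(X))` with a warning when it exceeds the rank
#'   budget.
#' @return an object of class `pls_model` with elements `R`, `Q` (SIMPLS
#'   weights and response loadings), `xmeans`, `ymeans`, `ncomp`, and
#'   `classes` (level names when `Y` was a factor).
#' @seealso [pls_rmsecv()]
#' @export
pls_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X)
  classes <- NULL
  if (is.factor(Y) || is.character(Y)) {
    Y <- as.factor(Y)
    classes <- levels(Y)
    Y <- class_indicator(Y)
  }
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 2)
  max_a <- min(nrow(X) - 1L, ncol(X))
  if (ncomp > max_a) {
    warning(sprintf("ncomp = %d exceeds the rank budget; clipped to %d",
                    ncomp, max_a))
    ncomp <- max_a
  }
  fit <- .simpls_fit_cpp(X, Y, as.integer(ncomp))
  fit$classes <- classes
  class(fit) <- "pls_model"
  fit
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS (SIMPLS) model: %d latent variable(s), %d band(s), %d response column(s)\n",
              x$ncomp, length(x$xmeans), length(x$ymeans)))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model` from [pls_fit()].
#' @param newdata numeric matrix with the band dimension the model was
#'   fitted on.
#' @param ncomp truncation; defaults to the fitted number of components.
#' @param ... unused.
#' @return fitted response matrix.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  ncomp <- min(ncomp, object$ncomp)
  B <- object$R[, seq_len(ncomp), drop = FALSE] %*%
    t(object$Q[, seq_len(ncomp), drop = FALSE])
  sweep(newdata, 2, object$xmeans) %*% B +
    matrix(object$ymeans, nrow(newdata), length(object$ymeans), byrow = TRUE)
}

#' Coefficient magnitude per band of a PLS model
#'
#' Euclidean norm, across response columns, of each band's row of the
#' regression coefficient matrix; the importance measure CARS ranks
#' bands by.
#'
#' @inheritParams predict.pls_model
#' @return numeric vector, one magnitude per band.
#' @export
pls_coef_magnitude <- function(object, ncomp = object$ncomp) {
  ncomp <- min(ncomp, object$ncomp)
  B <- object$R[, seq_len(ncomp), drop = FALSE] %*%
    t(object$Q[, seq_len(ncomp), drop = FALSE])
  sqrt(rowSums(B^2))
}

#' Cross-validated PLS with RMSECV-based component choice
#'
#' Encodes the class labels as an indicator matrix (PLS2), computes the
#' cross-validated root mean squared error of the indicator predictions
#' for every truncation 1..`ncomp`, picks the truncation minimising
#' RMSECV, and refits on the full data at that size.
#'
#' @param X numeric matrix, samples x bands.
#' @param y class labels (factor or coercible) or an already-encoded
#'   numeric response matrix.
#' @param ncomp maximum number of latent variables considered.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed for the fold assignment; `NULL` uses the
#'   current RNG stream.
#' @param foldid optional explicit fold labels (overrides `folds`/`seed`).
#' @return list with `model` (the refitted [pls_fit()] object), `rmsecv`
#'   (at the chosen truncation), `ncomp` (chosen truncation), and
#'   `rmsecv_path` (RMSECV for every truncation).
#' @export
pls_rmsecv <- function(X, y, ncomp, folds = 10, seed = NULL, foldid = NULL) {
  X <- as.matrix(X)
  Y <- if (is.matrix(y)) y else class_indicator(y)
  stopifnot(folds >= 2, nrow(X) == nrow(Y))
  max_a <- min(nrow(X) - 1L, ncol(X))
  if (ncomp > max_a) {
    warning(sprintf("ncomp = %d exceeds the rank budget; clipped to %d",
                    ncomp, max_a))
    ncomp <- max_a
  }
  if (is.null(foldid))
    foldid <- with_seed(seed, make_folds(nrow(X), folds))
  path <- as.numeric(.simpls_cv_rmsecv_cpp(X, Y, as.integer(ncomp),
                                           as.integer(foldid)))
  best <- which.min(path)
  model <- pls_fit(X, if (is.matrix(y)) y else as.factor(y), best)
  list(model = model, rmsecv = path[best], ncomp = best, rmsecv_path = path)
}

# RMSECV path only (no refit); hot path for CARS/IRIV.
pls_rmsecv_path <- function(X, Y, ncomp, foldid) {
  ncomp <- min(ncomp, nrow(X) - 1L, ncol(X))
  as.numeric(.simpls_cv_rmsecv_cpp(X, Y, as.integer(ncomp),
                                   as.integer(foldid)))
}
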