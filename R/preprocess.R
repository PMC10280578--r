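#' Standard normal variate transform
#'
#' Centres every spectrum by its own mean and scales by its own standard
#' deviation (sample sd, divisor n - 1), removing per-spectrum baseline
#' and gain without any reference spectrum.
#'
#' @param X numeric matrix, one spectrum per row.
#' @param divisor `"sample"` (n - 1, the default) or `"population"` (n).
#' @return matrix of the same shape; every row has mean 0 and unit sd
#'   under the chosen divisor.
#' @export
snv <- function(X, divisor = c("sample", "population")) {
  X <- as.matrix(X)
  divisor <- match.arg(divisor)
  mu <- rowMeans(X)
  ss <- rowSums((X - mu)^2)
  n <- ncol(X)
  s <- sqrt(ss / if (divisor == "sample") n - 1 else n)
  if (any(s < 1e-12)) {
    bad <- which(s < 1e-12)[1]
    stop_hyperseed("hyperseed_degenerate_spectrum",
                   "row %d is constant: SNV undefined", bad)
  }
  (X - mu) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum by ordinary least
#' squares, `x ~ a + b * reference`, and returns `(x - a) / b`, removing
#' per-spectrum multiplicative gain and additive offset. The reference is
#' the column mean of the fitted (training) matrix unless supplied; reuse
#' the returned reference on prediction spectra so no test information
#' leaks into the correction.
#'
#' @param X numeric matrix, one spectrum per row.
#' @param reference numeric vector of length `ncol(X)`, or `NULL` to use
#'   the column mean of `X`.
#' @param b_tol slopes with `|b|` below this are rejected (default 1e-12).
#' @return list with `X` (corrected matrix) and `reference` (the spectrum
#'   used); of class `msc_corrected`.
#' @export
msc <- function(X, reference = NULL, b_tol = 1e-12) {
  X <- as.matrix(X)
  if (is.null(reference)) reference <- colMeans(X)
  stopifnot(length(reference) == ncol(X))
  r0 <- reference - mean(reference)
  denom <- sum(r0^2)
  if (denom < b_tol)
    stop_hyperseed("hyperseed_scatter_fit_degenerate",
                   "reference spectrum is constant: slope unidentifiable")
  b <- as.vector((X - rowMeans(X)) %*% r0) / denom
  if (any(abs(b) < b_tol)) {
    bad <- which(abs(b) < b_tol)[1]
    stop_hyperseed("hyperseed_scatter_fit_degenerate",
                   "row %d: fitted slope |b| < %g", bad, b_tol)
  }
  a <- rowMeans(X) - b * mean(reference)
  structure(list(X = (X - a) / b, reference = as.numeric(reference)),
            class = "msc_corrected")
}

#' Savitzky-Golay first derivative
#'
#' First derivative of each spectrum by Savitzky-Golay local polynomial
#' filtering with unit (per-band-index) spacing. Edge points are fitted
#' with the same polynomial over the asymmetric end window, so
#' polynomials up to `polyorder` are differentiated exactly everywhere.
#'
#' @param X numeric matrix, one spectrum per row.
#' @param window odd number of filter points (default 5).
#' @param polyorder polynomial degree (default 2); must be < `window`.
#' @param deriv derivative order (default 1); must be <= `polyorder`.
#' @return matrix of the same shape holding the derivatives.
#' @export
sg1 <- function(X, window = 5, polyorder = 2, deriv = 1) {
  X <- as.matrix(X)
  if (window %% 2 == 0 || window <= polyorder)
    stop_hyperseed("hyperseed_config_error",
                   "window must be odd and > polyorder (got %d, %d)",
                   window, polyorder)
  if (deriv > polyorder)
    stop_hyperseed("hyperseed_config_error",
                   "derivative order %d exceeds polyorder %d", deriv,
                   polyorder)
  if (ncol(X) < window)
    stop_hyperseed("hyperseed_config_error",
                   "spectra have %d bands, fewer than the %d-point window",
                   ncol(X), window)
  t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window, m = deriv))
}

#' Fit / apply a spectral pretreatment with a frozen training state
#'
#' Thin dispatcher over [snv()], [msc()] and [sg1()] used by the pipeline:
#' `preprocess_fit()` learns any state from the training spectra (the MSC
#' reference), and `preprocess_apply()` applies the frozen transform to
#' further spectra, so prediction data never informs the pretreatment.
#'
#' @param X training spectra matrix.
#' @param method one of `"none"`, `"msc"`, `"snv"`, `"sg1"`.
#' @param sg_window,sg_polyorder,sg_deriv Savitzky-Golay settings (5/2/1
#'   by default).
#' @param msc_reference optional fixed MSC reference spectrum.
#' @return `preprocess_fit()`: an object of class `preprocess_model`;
#'   `preprocess_apply()`: the transformed matrix.
#' @export
preprocess_fit <- function(X, method = c("none", "msc", "snv", "sg1"),
                           sg_window = 5, sg_polyorder = 2, sg_deriv = 1,
                           msc_reference = NULL) {
  method <- match.arg(method)
  reference <- NULL
  if (method == "msc")
    reference <- msc_reference %||% colMeans(as.matrix(X))
  structure(list(method = method, reference = reference,
                 sg_window = sg_window, sg_polyorder = sg_polyorder,
                 sg_deriv = sg_deriv),
            class = "preprocess_model")
}

#' @rdname preprocess_fit
#' @param model a `preprocess_model` from `preprocess_fit()`.
#' @export
preprocess_apply <- function(model, X) {
  stopifnot(inherits(model, "preprocess_model"))
  X <- as.matrix(X)
  switch(model$method,
         none = X,
         snv = snv(X),
         msc = msc(X, reference = model$reference)$X,
         sg1 = sg1(X, model$sg_window, model$sg_polyorder, model$sg_deriv))
}
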