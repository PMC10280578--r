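#' Exponential decay keep-ratio of CARS
#'
#' Fraction of bands retained by forced selection at Monte Carlo run `i`
#' of `n_runs`: `r_i = a * exp(-k * i)` with the boundary conditions
#' `r_1 = 1` (all `p` bands survive the first run) and
#' `r_N = 2 / p` (only two bands can survive the last), giving
#' `a = (p / 2)^(1 / (N - 1))` and `k = log(p / 2) / (N - 1)`.
#'
#' @param i run index, `1 <= i <= n_runs`.
#' @param n_runs total Monte Carlo runs.
#' @param p total number of candidate bands (>= 3).
#' @return keep fraction in (0, 1].
#' @export
edf_keep_ratio <- function(i, n_runs, p) {
  stopifnot(all(i >= 1), all(i <= n_runs), p >= 3, n_runs >= 2)
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * i)
}

#' CARS configuration
#'
#' @param n_runs Monte Carlo sampling runs (default 80).
#' @param max_lv largest number of PLS latent variables (default 25).
#' @param cv_folds cross-validation folds for RMSECV (default 10).
#' @param mc_fraction fraction of training rows drawn (without
#'   replacement) as each run's calibration subset (default 0.8).
#' @param seed integer RNG seed; fixes the whole selection path.
#' @return list of class `cars_config`.
#' @export
cars_config <- function(n_runs = 80, max_lv = 25, cv_folds = 10,
                        mc_fraction = 0.8, seed = 1) {
  stopifnot(n_runs >= 2, mc_fraction > 0, mc_fraction < 1, max_lv >= 1,
            cv_folds >= 2)
  structure(list(n_runs = n_runs, max_lv = max_lv, cv_folds = cv_folds,
                 mc_fraction = mc_fraction, seed = seed),
            class = "cars_config")
}

#' Competitive adaptive reweighted sampling
#'
#' Wavelength selection by CARS: each Monte Carlo run draws a calibration
#' subset of the rows, fits a PLS model on the currently surviving bands
#' (latent-variable count picked by cross-validated RMSECV), ranks bands
#' by the magnitude of their regression coefficients, keeps the top
#' fraction dictated by the exponentially decaying [edf_keep_ratio()]
#' (forced selection), and then resamples among the kept bands with
#' probability proportional to coefficient magnitude (adaptive reweighted
#' sampling). Every run's surviving subset is scored by RMSECV on the
#' full training rows; the subset with the smallest RMSECV wins.
#'
#' @param X preprocessed training spectra (matrix or [spectra_table()]).
#' @param y class labels, one per row; >= 2 classes.
#' @param config a [cars_config()].
#' @return an object of class `variable_subset`: list with `indices`
#'   (sorted band indices), `method`, `rmsecv` of the winning subset, and
#'   a per-run `trace` data frame (run, subset size, RMSECV, chosen LVs).
#' @export
cars_select <- function(X, y, config = cars_config()) {
  if (inherits(X, "spectra_table")) {
    y <- X$labels
    X <- X$X
  }
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nlevels(y) >= 2, nrow(X) == length(y))
  Y <- class_indicator(y)
  p <- ncol(X)
  n <- nrow(X)
  with_seed(config$seed, {
    current <- seq_len(p)
    n_cal <- max(2L, round(config$mc_fraction * n))
    # one CV partition scores every run's subset, so the argmin over
    # runs compares subsets, not fold assignments
    foldid_full <- make_folds(n, config$cv_folds)
    # the full band set competes as run 0, so the winner can never score
    # worse than the model using every band
    lv0 <- min(config$max_lv, p, n - 1L)
    path0 <- pls_rmsecv_path(X, Y, lv0, foldid_full)
    trace <- data.frame(run = 0L, n_vars = p, rmsecv = min(path0),
                        ncomp = which.min(path0))
    subsets <- list(`0` = seq_len(p))
    for (i in seq_len(config$n_runs)) {
      if (length(current) < 2) break
      cal <- sample(n, n_cal)
      # guard: a calibration draw must contain >= 2 classes for PLS-DA
      while (length(unique(y[cal])) < 2) cal <- sample(n, n_cal)
      Xc <- X[cal, current, drop = FALSE]
      Yc <- Y[cal, , drop = FALSE]
      lv <- min(config$max_lv, length(current), n_cal - 1L)
      foldid <- make_folds(n_cal, config$cv_folds)
      path <- pls_rmsecv_path(Xc, Yc, lv, foldid)
      a_star <- which.min(path)
      fit <- pls_fit(Xc, Yc, a_star)
      w <- pls_coef_magnitude(fit)
      # forced selection by the exponential decay function; the target
      # count r_i * p refers to the full band count, so early runs keep
      # the whole current set
      target_n <- max(2L, ceiling(edf_keep_ratio(i, config$n_runs, p) * p))
      keep_n <- min(length(current), target_n)
      ord <- order(w, decreasing = TRUE)
      kept <- ord[seq_len(keep_n)]
      # adaptive reweighted sampling: target_n weighted draws with
      # replacement among the kept bands; duplicates collapse
      wk <- w[kept]
      if (sum(wk) <= 0) wk <- rep(1, length(kept))
      drawn <- unique(sample(kept, size = target_n, replace = TRUE,
                             prob = wk))
      current <- sort(current[drawn])
      if (length(current) < 2) break
      # score the run's subset on all training rows
      lv_full <- min(config$max_lv, length(current), n - 1L)
      path_full <- pls_rmsecv_path(X[, current, drop = FALSE], Y, lv_full,
                                   foldid_full)
      trace <- rbind(trace,
                     data.frame(run = i, n_vars = length(current),
                                rmsecv = min(path_full),
                                ncomp = which.min(path_full)))
      subsets[[as.character(i)]] <- current
    }
    best <- trace$run[which.min(trace$rmsecv)]
    structure(list(indices = subsets[[as.character(best)]], method = "cars",
                   rmsecv = min(trace$rmsecv), trace = trace),
              class = "variable_subset")
  })
}

#' @export
print.variable_subset <- function(x, ...) {
  cat(sprintf("variable_subset (%s): %d band(s), RMSECV %.4f\n",
              x$method, length(x$indices), x$rmsecv))
  invisible(x)
}
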