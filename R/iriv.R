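#' IRIV configuration
#'
#' @param max_lv largest number of PLS latent variables (default 40).
#' @param cv_folds cross-validation folds for RMSECV (default 11).
#' @param n_models random-subset models per round (default 1000).
#' @param alpha significance level of the Mann-Whitney test that
#'   separates strong from weak (and interfering from uninformative)
#'   variables (default 0.05).
#' @param max_rounds safety cap on elimination rounds (default 50).
#' @param seed integer RNG seed; fixes the whole selection path.
#' @return list of class `iriv_config`.
#' @export
iriv_config <- function(max_lv = 40, cv_folds = 11, n_models = 1000,
                        alpha = 0.05, max_rounds = 50, seed = 1) {
  stopifnot(n_models >= 100, alpha > 0, alpha < 1, max_lv >= 1,
            cv_folds >= 2)
  structure(list(max_lv = max_lv, cv_folds = cv_folds,
                 n_models = n_models, alpha = alpha,
                 max_rounds = max_rounds, seed = seed),
            class = "iriv_config")
}

#' Iteratively retaining informative variables
#'
#' Wavelength selection by model population analysis. Each round draws a
#' binary inclusion matrix (`n_models` rows, one column per surviving
#' band, each cell 1 with probability 1/2), scores every row's band
#' subset by cross-validated RMSECV of a PLS-DA model, and assesses each
#' band by comparing the RMSECV distribution of the models that include
#' it against the models that exclude it: `DMEAN = mean(without) -
#' mean(with)`, with a two-sided Mann-Whitney U test for significance.
#' Bands are classified as strong (`DMEAN > 0`, significant), weak
#' (`DMEAN > 0`, not significant), uninformative (`DMEAN <= 0`, not
#' significant) or interfering (`DMEAN <= 0`, significant); the last two
#' groups are dropped and the round repeats until no band is dropped.
#' A final backward elimination then removes surviving weak bands one at
#' a time as long as the full-model RMSECV does not worsen.
#'
#' @param X preprocessed training spectra (matrix or [spectra_table()]).
#' @param y class labels, one per row; >= 2 classes.
#' @param config an [iriv_config()].
#' @return an object of class `variable_subset`: `indices` (sorted band
#'   indices), `method`, `rmsecv` of the final subset, per-round `trace`,
#'   and `classification` of the last round.
#' @export
iriv_select <- function(X, y, config = iriv_config()) {
  if (inherits(X, "spectra_table")) {
    y <- X$labels
    X <- X$X
  }
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nlevels(y) >= 2, nrow(X) == length(y))
  Y <- class_indicator(y)
  n <- nrow(X)
  with_seed(config$seed, {
    current <- seq_len(ncol(X))
    trace <- data.frame(round = integer(0), n_vars = integer(0),
                        n_strong = integer(0), n_weak = integer(0),
                        n_removed = integer(0), mean_rmsecv = numeric(0))
    classes_last <- NULL
    for (round in seq_len(config$max_rounds)) {
      p <- length(current)
      if (p <= 2) break
      M <- matrix(runif(config$n_models * p) < 0.5, config$n_models, p)
      # every model needs >= 2 bands; every band must appear in both arms
      short <- rowSums(M) < 2
      while (any(short)) {
        M[short, ] <- matrix(runif(sum(short) * p) < 0.5, sum(short), p)
        short <- rowSums(M) < 2
      }
      csum <- colSums(M)
      fix <- which(csum == 0 | csum == config$n_models)
      for (j in fix) M[sample(config$n_models, 1), j] <- csum[j] == 0
      foldid <- make_folds(n, config$cv_folds)
      rmse <- vapply(seq_len(config$n_models), function(k) {
        vars <- current[M[k, ]]
        min(pls_rmsecv_path(X[, vars, drop = FALSE], Y,
                            min(config$max_lv, length(vars)), foldid))
      }, numeric(1))
      dmean <- numeric(p)
      pval <- numeric(p)
      for (j in seq_len(p)) {
        v1 <- rmse[M[, j]]
        v0 <- rmse[!M[, j]]
        dmean[j] <- mean(v0) - mean(v1)
        pval[j] <- suppressWarnings(
          stats::wilcox.test(v0, v1, exact = FALSE)$p.value)
      }
      cls <- ifelse(dmean > 0,
                    ifelse(pval < config$alpha, "strong", "weak"),
                    ifelse(pval < config$alpha, "interfering",
                           "uninformative"))
      keep <- cls %in% c("strong", "weak")
      trace <- rbind(trace, data.frame(
        round = round, n_vars = p, n_strong = sum(cls == "strong"),
        n_weak = sum(cls == "weak"), n_removed = sum(!keep),
        mean_rmsecv = mean(rmse)))
      classes_last <- data.frame(index = current, class = cls,
                                 dmean = dmean, p_value = pval)
      if (!any(keep))
        stop_hyperseed("hyperseed_selection_failed",
                       "IRIV eliminated every variable; consider a larger alpha or n_models")
      if (all(keep)) break
      current <- current[keep]
    }
    # backward elimination of the surviving weak variables
    foldid <- make_folds(n, config$cv_folds)
    score <- function(vars)
      min(pls_rmsecv_path(X[, vars, drop = FALSE], Y,
                          min(config$max_lv, length(vars)), foldid))
    base <- score(current)
    weak <- if (is.null(classes_last)) integer(0) else
      intersect(current, classes_last$index[classes_last$class == "weak"])
    repeat {
      weak <- intersect(weak, current)
      if (length(weak) == 0 || length(current) <= 2) break
      cand <- vapply(weak, function(v) score(setdiff(current, v)),
                     numeric(1))
      best <- which.min(cand)
      if (cand[best] <= base) {
        current <- setdiff(current, weak[best])
        base <- cand[best]
        weak <- weak[-best]
      } else break
    }
    structure(list(indices = sort(current), method = "iriv",
                   rmsecv = base, trace = trace,
                   classification = classes_last),
              class = "variable_subset")
  })
}
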