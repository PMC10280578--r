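#' Kennard-Stone sample partitioning
#'
#' Deterministic max-min split of a sample set into training and
#' prediction sets: the training set is seeded with the pair of samples
#' at the greatest Euclidean distance, then repeatedly extended with the
#' sample whose minimum distance to the already-selected set is largest,
#' until `n_train` samples are selected. Ties are broken by the lowest
#' row index, so the partition is fully reproducible.
#'
#' @param X numeric matrix (samples x bands) or a [spectra_table()].
#' @param n_train number of training samples, `2 <= n_train <= nrow(X)`.
#' @return an object of class `ks_partition`: list with `train_idx` (in
#'   selection order), `test_idx` (ascending), `n_train`.
#' @export
ks_split <- function(X, n_train) {
  if (inherits(X, "spectra_table")) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_train < 2 || n_train > n)
    stop_hyperseed("hyperseed_config_error",
                   "n_train must lie in [2, %d], got %d", n, n_train)
  D <- as.matrix(stats::dist(X))
  far <- which(D == max(D), arr.ind = TRUE)
  # lowest-index pair among the maxima
  far <- far[order(pmin(far[, 1], far[, 2]), pmax(far[, 1], far[, 2])), ,
             drop = FALSE][1, ]
  if (max(D) == 0)
    warning("all samples coincide; farthest pair resolved by index order")
  sel <- sort(as.integer(far))
  if (sum(D == max(D)) > 2 && max(D) > 0) {
    tied <- sum(D[upper.tri(D)] == max(D)) > 1
    if (tied) warning("farthest pair is tied; lowest-index pair selected")
  }
  mind <- unname(pmin(D[, sel[1]], D[, sel[2]]))
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- which.max(mind)  # which.max takes the first (lowest-index) max
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  structure(list(train_idx = sel, test_idx = setdiff(seq_len(n), sel),
                 n_train = n_train),
            class = "ks_partition")
}

#' @export
print.ks_partition <- function(x, ...) {
  cat(sprintf("ks_partition: %d training / %d prediction sample(s)\n",
              length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

#' Per-class (stratified) Kennard-Stone split
#'
#' Runs [ks_split()] inside every class and pools the result, allocating
#' training slots proportionally to class size.
#'
#' @inheritParams ks_split
#' @param labels class label per row.
#' @return a `ks_partition`.
#' @export
ks_split_stratified <- function(X, labels, n_train) {
  if (inherits(X, "spectra_table")) {
    labels <- X$labels
    X <- X$X
  }
  labels <- as.factor(labels)
  n <- nrow(X)
  per <- round(table(labels) / n * n_train)
  # adjust rounding drift on the largest class
  per[which.max(per)] <- per[which.max(per)] + (n_train - sum(per))
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    part <- ks_split(X[idx, , drop = FALSE], per[[cl]])
    train <- c(train, idx[part$train_idx])
  }
  structure(list(train_idx = train, test_idx = setdiff(seq_len(n), train),
                 n_train = n_train),
            class = "ks_partition")
}
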