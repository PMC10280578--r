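#' Construct a spectra table
#'
#' The central flat container: one row per seed, one column per band,
#' with the wavelength grid and the variety label of every seed.
#'
#' @param X numeric matrix, samples x bands; no missing values.
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing, length `ncol(X)`. Default: uniform grid over 400-1000 nm.
#' @param labels class labels, one per row (factor or coercible).
#' @param sample_ids optional character ids, one per row.
#' @return an object of class `spectra_table`: a list with elements `X`,
#'   `wavelengths`, `labels`, `sample_ids`.
#' @export
spectra_table <- function(X, wavelengths = default_wavelengths(ncol(X)),
                          labels, sample_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X))
    stop_hyperseed("hyperseed_format_error", "spectra contain missing values")
  if (length(wavelengths) != ncol(X))
    stop_hyperseed("hyperseed_format_error",
                   "wavelength count (%d) != band count (%d)",
                   length(wavelengths), ncol(X))
  if (any(diff(wavelengths) <= 0))
    stop_hyperseed("hyperseed_format_error",
                   "wavelengths must be strictly increasing")
  labels <- as.factor(labels)
  if (length(labels) != nrow(X))
    stop_hyperseed("hyperseed_format_error",
                   "label count (%d) != sample count (%d)",
                   length(labels), nrow(X))
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%03d", seq_len(nrow(X)))
  structure(list(X = X, wavelengths = as.numeric(wavelengths),
                 labels = labels, sample_ids = as.character(sample_ids)),
            class = "spectra_table")
}

#' Default wavelength grid
#'
#' Uniform grid of `n` band centres spanning `range` (nm); the instrument
#' layout this package targets has 176 bands over 400-1000 nm.
#'
#' @param n number of bands.
#' @param range two-element nm range.
#' @return numeric vector of length `n`.
#' @export
default_wavelengths <- function(n = 176, range = c(400, 1000)) {
  seq(range[1], range[2], length.out = n)
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("spectra_table: %d seed(s) x %d band(s), %.0f-%.0f nm, %d class(es)\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths),
              nlevels(x$labels)))
  print(table(variety = x$labels))
  invisible(x)
}

#' @export
dim.spectra_table <- function(x) dim(x$X)

#' Read per-variety spectra files into one table
#'
#' Reads the deposited supplementary layout: one numeric file per
#' variety, 60 rows (seeds) x 176 columns (bands), with the file-to-label
#' mapping given explicitly rather than parsed from filenames. The
#' delimiter is sniffed (comma / semicolon / whitespace); an optional
#' non-numeric header row is skipped.
#'
#' @param paths character vector of file paths, one per variety, or a
#'   manifest list/path accepted by [read_manifest()].
#' @param labels class label per file; defaults to the manifest labels or
#'   `names(paths)`.
#' @param n_rows,n_cols expected per-file shape (default 60 x 176); set
#'   either to `NA` to accept any shape.
#' @param wavelengths wavelength grid; default uniform over 400-1000 nm.
#' @return a [spectra_table()] with files stacked in the given order.
#' @export
read_spectra_table <- function(paths, labels = names(paths), n_rows = 60,
                               n_cols = 176,
                               wavelengths = NULL) {
  if (length(paths) == 1 && is.character(paths) &&
      grepl("\\.ya?ml$", paths)) {
    man <- read_manifest(paths)
    paths <- man$paths
    labels <- man$labels
  }
  if (is.null(labels))
    stop_hyperseed("hyperseed_format_error",
                   "no class labels given for the spectra files")
  stopifnot(length(labels) == length(paths))
  if (anyDuplicated(paths))
    warning("a file is listed for more than one class; rows are duplicated under distinct labels")
  mats <- lapply(seq_along(paths), function(i) {
    m <- read_numeric_table(paths[[i]])
    if (!is.na(n_rows) && nrow(m) != n_rows)
      stop_hyperseed("hyperseed_format_error",
                     "file '%s': expected %d rows, found %d",
                     paths[[i]], n_rows, nrow(m))
    if (!is.na(n_cols) && ncol(m) != n_cols)
      stop_hyperseed("hyperseed_format_error",
                     "file '%s': expected %d columns, found %d",
                     paths[[i]], n_cols, ncol(m))
    m
  })
  nb <- unique(vapply(mats, ncol, 1L))
  if (length(nb) != 1)
    stop_hyperseed("hyperseed_format_error",
                   "files disagree on band count: %s",
                   paste(nb, collapse = ", "))
  X <- do.call(rbind, mats)
  if (is.null(wavelengths)) wavelengths <- default_wavelengths(nb)
  spectra_table(X, wavelengths,
                labels = rep(as.character(labels),
                             vapply(mats, nrow, 1L)))
}

# Sniff the delimiter and parse a numeric matrix; names the offending
# cell on failure.
read_numeric_table <- function(path) {
  if (!file.exists(path))
    stop_hyperseed("hyperseed_format_error", "file '%s' not found", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", first)) "," else if (grepl(";", first)) ";" else ""
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  # drop a header row of band names if present
  num1 <- suppressWarnings(as.numeric(unlist(df[1, ])))
  if (anyNA(num1)) df <- df[-1, , drop = FALSE]
  m <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  m <- matrix(m, nrow = nrow(df))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_hyperseed("hyperseed_format_error",
                   "file '%s': non-numeric cell at row %d, column %d",
                   path, bad[1], bad[2])
  }
  m
}

#' Write a spectra table as one CSV
#'
#' Canonical on-disk form: one row per seed, the band columns only (no
#' header, no label column); labels travel in the manifest or alongside.
#' [write_supplementary_format()] writes the per-variety layout instead.
#'
#' @param table a [spectra_table()] or numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(table, path) {
  X <- if (inherits(table, "spectra_table")) table$X else as.matrix(table)
  utils::write.table(X, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a file-to-variety manifest
#'
#' YAML mapping with a `files` list of `{path, label}` entries; relative
#' paths are resolved against the manifest's directory.
#'
#' @param path manifest file.
#' @return list with `paths` and `labels`.
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$files))
    stop_hyperseed("hyperseed_format_error",
                   "manifest '%s' has no 'files' entry", path)
  paths <- vapply(man$files, function(f) f$path, "")
  labels <- vapply(man$files, function(f) as.character(f$label), "")
  rel <- !grepl("^(/|[A-Za-z]:)", paths)
  paths[rel] <- file.path(dirname(path), paths[rel])
  list(paths = paths, labels = labels)
}
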