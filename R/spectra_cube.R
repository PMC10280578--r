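#' Construct a hyperspectral cube
#'
#' A 3-D reflectance (or raw intensity) image: two spatial axes and one
#' spectral axis, each pixel carrying a full spectrum.
#'
#' @param values numeric 3-D array, dimensions (row, col, band).
#' @param wavelengths band centres in nm, strictly increasing, length
#'   `dim(values)[3]`.
#' @return an object of class `spectral_cube`.
#' @export
spectral_cube <- function(values,
                          wavelengths = default_wavelengths(dim(values)[3])) {
  values <- as.array(values)
  if (length(dim(values)) != 3)
    stop_hyperseed("hyperseed_format_error", "cube must be a 3-D array")
  if (length(wavelengths) != dim(values)[3])
    stop_hyperseed("hyperseed_format_error",
                   "wavelength count (%d) != band count (%d)",
                   length(wavelengths), dim(values)[3])
  if (any(diff(wavelengths) <= 0))
    stop_hyperseed("hyperseed_format_error",
                   "wavelengths must be strictly increasing")
  structure(list(values = values, wavelengths = as.numeric(wavelengths)),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("spectral_cube: %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Black/white reflectance correction
#'
#' Converts raw sensor intensity to reflectance using a dark-current
#' frame and a white-reference frame:
#' `R = (I_raw - I_dark) / (I_white - I_dark)`, elementwise. The
#' reference frames may be 2-D (one value per pixel, shared across
#' bands) or full 3-D stacks.
#'
#' @param raw a `spectral_cube` of raw intensities.
#' @param white,dark reference frames: arrays matching the cube's spatial
#'   (and optionally spectral) dimensions, or scalars.
#' @return a `spectral_cube` of reflectance values.
#' @export
reflectance_correct <- function(raw, white, dark) {
  stopifnot(inherits(raw, "spectral_cube"))
  d <- dim(raw$values)
  expand <- function(f, what) {
    f <- if (length(f) == 1) array(f, d) else as.array(f)
    if (length(dim(f)) == 2) {
      if (!all(dim(f) == d[1:2]))
        stop_hyperseed("hyperseed_format_error",
                       "%s frame is %s but the cube is %d x %d", what,
                       paste(dim(f), collapse = " x "), d[1], d[2])
      f <- array(rep(f, d[3]), d)
    }
    if (!all(dim(f) == d))
      stop_hyperseed("hyperseed_format_error",
                     "%s frame does not match the cube dimensions", what)
    f
  }
  W <- expand(white, "white")
  D <- expand(dark, "dark")
  denom <- W - D
  bad <- which(abs(denom) < .Machine$double.eps)
  if (length(bad)) {
    px <- arrayInd(bad[1], d)
    stop_hyperseed("hyperseed_correction_degenerate",
                   "white == dark at pixel (%d, %d), band %d: correction undefined",
                   px[1], px[2], px[3])
  }
  spectral_cube((raw$values - D) / denom, raw$wavelengths)
}

#' Segment seeds from a corrected cube by grey-level thresholding
#'
#' Collapses the cube to a grey image (per-pixel mean reflectance over
#' all bands by default, or a single band), binarises it at `threshold`
#' (pixels strictly greater than the threshold become foreground), and
#' labels 8-connected components, dropping specks below `min_pixels`.
#'
#' @param cube a reflectance `spectral_cube`.
#' @param threshold grey cutoff in (0, 1); 0.1 separates seeds from a
#'   low-reflectance background panel.
#' @param min_pixels smallest component kept (default 30).
#' @param gray_band optional band index: use that single band as the grey
#'   image instead of the across-band mean.
#' @return an object of class `seed_mask`: list with `labels` (integer
#'   matrix, 0 = background, k > 0 = seed k), `n_seeds`, `threshold`.
#' @export
segment_seeds <- function(cube, threshold = 0.1, min_pixels = 30,
                          gray_band = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (threshold <= 0 || threshold >= 1)
    stop_hyperseed("hyperseed_config_error",
                   "threshold must lie in (0, 1), got %g", threshold)
  gray <- if (is.null(gray_band)) {
    rowMeans(matrix(cube$values, prod(dim(cube$values)[1:2])))
  } else {
    as.vector(cube$values[, , gray_band])
  }
  gray <- matrix(gray, dim(cube$values)[1], dim(cube$values)[2])
  labels <- label_components(gray > threshold)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_pixels)
  if (length(keep) == 0)
    stop_hyperseed("hyperseed_empty_mask",
                   "no seed region above threshold %g with >= %d pixels",
                   threshold, min_pixels)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  labels[labels > 0] <- relab[labels[labels > 0]]
  structure(list(labels = labels, n_seeds = length(keep),
                 threshold = threshold),
            class = "seed_mask")
}

# 8-connected component labelling by iterative flood fill.
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in which(fg)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((i - 1L) %% nr) + 1L
      cc <- ((i - 1L) %/% nr) + 1L
      nb_r <- r + off_r
      nb_c <- cc + off_c
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- nb[fg[nb] & labels[nb] == 0L]
      labels[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  labels
}

#' @export
print.seed_mask <- function(x, ...) {
  cat(sprintf("seed_mask: %d seed(s), threshold %g, %d x %d pixels\n",
              x$n_seeds, x$threshold, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Mean spectrum of one segmented seed
#'
#' The per-band arithmetic mean over the m pixels of the seed's region
#' of interest — the seed's spectral signature.
#'
#' @param cube a reflectance `spectral_cube`.
#' @param mask a `seed_mask` from [segment_seeds()].
#' @param seed_id positive label present in the mask.
#' @return numeric vector of length `length(cube$wavelengths)`.
#' @export
mean_spectrum <- function(cube, mask, seed_id) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(mask, "seed_mask"))
  px <- which(mask$labels == seed_id)
  if (length(px) == 0)
    stop_hyperseed("hyperseed_lookup_error",
                   "seed id %s not present in the mask", format(seed_id))
  npix <- prod(dim(cube$values)[1:2])
  flat <- matrix(cube$values, npix)
  colMeans(flat[px, , drop = FALSE])
}

#' Extract the spectra of every seed in a mask
#'
#' @inheritParams mean_spectrum
#' @param labels optional class label applied to every seed (e.g. the
#'   variety on the tray).
#' @return a [spectra_table()], one row per seed in label order.
#' @export
extract_seed_spectra <- function(cube, mask, labels = "unknown") {
  X <- t(vapply(seq_len(mask$n_seeds),
                function(k) mean_spectrum(cube, mask, k),
                numeric(length(cube$wavelengths))))
  spectra_table(X, cube$wavelengths, labels = rep_len(labels, mask$n_seeds))
}
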