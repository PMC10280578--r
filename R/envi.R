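#' Read an ENVI-style hyperspectral cube
#'
#' Minimal reader for the band-sequential / band-interleaved binary
#' format commonly written by imaging spectrometers: a text header
#' (`.hdr`, `key = value` pairs) next to a raw binary file. Supported:
#' interleaves `bsq`, `bil`, `bip`; data types 4 (float32), 5 (float64),
#' 2 (int16), 12 (uint16); both byte orders. The header's `wavelength`
#' block, when present, overrides the default 400-1000 nm grid.
#'
#' @param path path to the binary file, or to the `.hdr` (the companion
#'   file is found by swapping the extension).
#' @return a [spectral_cube()] with dimensions (lines, samples, bands).
#' @export
read_envi <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  bin_path <- if (grepl("\\.hdr$", path)) sub("\\.hdr$", "", path) else path
  if (!file.exists(bin_path)) bin_path <- sub("\\.hdr$", ".dat", hdr_path)
  if (!file.exists(hdr_path) || !file.exists(bin_path))
    stop_hyperseed("hyperseed_format_error",
                   "cannot locate ENVI header/binary pair for '%s'", path)
  hdr <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop_hyperseed("hyperseed_format_error",
                   "ENVI header '%s' lacks field(s): %s", hdr_path,
                   paste(miss, collapse = ", "))
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  dtype <- as.integer(hdr$`data type`)
  sizes <- c(`2` = 2L, `4` = 4L, `5` = 8L, `12` = 2L)
  what <- c(`2` = "integer", `4` = "double", `5` = "double",
            `12` = "integer")
  if (!as.character(dtype) %in% names(sizes))
    stop_hyperseed("hyperseed_format_error",
                   "unsupported ENVI data type %d", dtype)
  endian <- if (identical(hdr$`byte order`, "1")) "big" else "little"
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what[[as.character(dtype)]], n = ns * nl * nb,
               size = sizes[[as.character(dtype)]], endian = endian,
               signed = dtype != 12L)
  if (length(v) != ns * nl * nb)
    stop_hyperseed("hyperseed_format_error",
                   "'%s' holds %d values; header promises %d", bin_path,
                   length(v), ns * nl * nb)
  # ENVI stores row-major within a line; fold to (line, sample, band)
  cube <- switch(tolower(hdr$interleave),
    bsq = aperm(array(v, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3, 2, 1)),
    stop_hyperseed("hyperseed_format_error",
                   "unsupported interleave '%s'", hdr$interleave))
  wl <- if (!is.null(hdr$wavelength)) {
    as.numeric(strsplit(gsub("[{}\n]", "", hdr$wavelength), ",")[[1]])
  } else default_wavelengths(nb)
  spectral_cube(cube, wl)
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- sub("^ENVI\\s*", "", txt)
  # join brace-delimited blocks onto one logical line
  out <- list()
  for (m in regmatches(txt, gregexpr(
    "[A-Za-z][A-Za-z0-9 ]*=\\s*(\\{[^}]*\\}|[^\n]*)", txt))[[1]]) {
    key <- trimws(sub("=.*", "", m))
    val <- trimws(sub("^[^=]*=", "", m))
    out[[tolower(key)]] <- val
  }
  out
}

#' Write a cube in ENVI band-sequential format
#'
#' @param cube a [spectral_cube()].
#' @param path output binary path; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$values)
  v <- switch(interleave,
              bsq = aperm(cube$values, c(2, 1, 3)),
              bil = aperm(cube$values, c(2, 3, 1)),
              bip = aperm(cube$values, c(3, 2, 1)))
  con <- file(path, "wb")
  writeBin(as.vector(v), con, size = 8, endian = "little")
  close(con)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]), sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]), "data type = 5",
           sprintf("interleave = %s", interleave), "byte order = 0",
           sprintf("wavelength = {%s}",
                   paste(format(cube$wavelengths, trim = TRUE),
                         collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}
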