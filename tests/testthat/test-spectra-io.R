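test_that("reflectance correction maps the reference frames to 0, 1 and midpoints to 0.5", {
  d <- c(4, 5, 6)
  dark <- array(100, d)
  white <- array(900, d)
  raw_dark <- spectral_cube(dark)
  raw_white <- spectral_cube(white)
  raw_mid <- spectral_cube((dark + white) / 2)
  expect_equal(reflectance_correct(raw_dark, white, dark)$values,
               array(0, d))
  expect_equal(reflectance_correct(raw_white, white, dark)$values,
               array(1, d))
  expect_equal(reflectance_correct(raw_mid, white, dark)$values,
               array(0.5, d))
})

test_that("reflectance correction is invariant to a common positive gain and accepts 2-D frames", {
  set.seed(7)
  d <- c(3, 4, 5)
  raw <- array(runif(prod(d), 200, 800), d)
  white <- array(runif(prod(d), 900, 1000), d)
  dark <- array(runif(prod(d), 0, 50), d)
  r1 <- reflectance_correct(spectral_cube(raw), white, dark)
  r2 <- reflectance_correct(spectral_cube(raw * 3.7), white * 3.7,
                            dark * 3.7)
  expect_equal(r1$values, r2$values)
  # 2-D frames broadcast across bands
  w2 <- matrix(1000, d[1], d[2])
  d2 <- matrix(10, d[1], d[2])
  r3 <- reflectance_correct(spectral_cube(raw), w2, d2)
  expect_equal(r3$values, (raw - 10) / 990)
})

test_that("a zero denominator raises a correction-degenerate error naming the pixel", {
  d <- c(2, 2, 3)
  white <- array(500, d)
  dark <- array(100, d)
  white[2, 1, 2] <- 100
  err <- expect_error(
    reflectance_correct(spectral_cube(array(300, d)), white, dark),
    class = "hyperseed_correction_degenerate")
  expect_match(conditionMessage(err), "\\(2, 1\\)")
})

test_that("segmentation finds the constructed seeds and honours the size filter", {
  cube <- two_seed_cube()
  mask <- segment_seeds(cube, threshold = 0.1)
  expect_s3_class(mask, "seed_mask")
  expect_identical(mask$n_seeds, 2L)
  # all-background cube
  empty <- spectral_cube(array(0.01, c(10, 10, 4)))
  expect_error(segment_seeds(empty, 0.1), class = "hyperseed_empty_mask")
  # one 25-pixel seed is rejected by min_pixels = 30
  small <- array(0.01, c(12, 12, 4))
  small[4:8, 4:8, ] <- 0.8
  expect_error(segment_seeds(spectral_cube(small), 0.1, min_pixels = 30),
               class = "hyperseed_empty_mask")
  expect_identical(segment_seeds(spectral_cube(small), 0.1,
                                 min_pixels = 25)$n_seeds, 1L)
})

test_that("segmentation is monotone in the threshold and respects 8-connectivity", {
  set.seed(3)
  a <- array(runif(15 * 15 * 3), c(15, 15, 3))
  cube <- spectral_cube(a)
  fg <- function(th) {
    m <- tryCatch(segment_seeds(cube, th, min_pixels = 1)$labels > 0,
                  error = function(e) matrix(FALSE, 15, 15))
    m
  }
  for (th in c(0.2, 0.4, 0.6)) {
    lo <- fg(th)
    hi <- fg(th + 0.2)
    expect_true(all(lo[hi]))  # raising the threshold never adds pixels
  }
  # two diagonally-touching pixels form one 8-connected component
  diag_img <- array(0.01, c(5, 5, 2))
  diag_img[2, 2, ] <- 0.9
  diag_img[3, 3, ] <- 0.9
  mask <- segment_seeds(spectral_cube(diag_img), 0.1, min_pixels = 1)
  expect_identical(mask$n_seeds, 1L)
})

test_that("mean spectra average the region and a union of regions averages by pixel count", {
  cube <- two_seed_cube(nb = 6)
  mask <- segment_seeds(cube, 0.1)
  s1 <- mean_spectrum(cube, mask, 1)
  expect_length(s1, 6)
  expect_equal(s1, rep(0.8, 6))  # identical pixels return their spectrum
  # two-pixel region with band values 0.2 and 0.4 averages to 0.3
  a <- array(0.01, c(4, 4, 3))
  a[2, 2, ] <- 0.2
  a[2, 3, ] <- 0.4
  cube2 <- spectral_cube(a)
  mask2 <- segment_seeds(cube2, 0.1, min_pixels = 1)
  expect_equal(mean_spectrum(cube2, mask2, 1)[1], 0.3)
  # unknown id
  expect_error(mean_spectrum(cube, mask, 99),
               class = "hyperseed_lookup_error")
  # union property: pooled mean is the pixel-count-weighted mean
  m1 <- sum(mask$labels == 1)
  m2 <- sum(mask$labels == 2)
  s2 <- mean_spectrum(cube, mask, 2)
  pooled_mask <- mask
  pooled_mask$labels[pooled_mask$labels == 2] <- 1L
  pooled <- mean_spectrum(cube, pooled_mask, 1)
  expect_equal(pooled, (m1 * s1 + m2 * s2) / (m1 + m2))
})

test_that("176-band cubes yield 176-point seed spectra", {
  a <- array(0.01, c(8, 8, 176))
  a[3:6, 3:6, ] <- 0.7
  cube <- spectral_cube(a)
  mask <- segment_seeds(cube, 0.1, min_pixels = 4)
  expect_length(mean_spectrum(cube, mask, 1), 176)
})

test_that("per-variety files round-trip through the supplementary layout", {
  tab <- small_table(seed = 2, n_per_class = 5, n_bands = 30)
  dir <- withr_local_tempdir()
  manifest <- write_supplementary_format(tab, dir)
  back <- read_spectra_table(manifest, n_rows = 5, n_cols = 30,
                             wavelengths = tab$wavelengths)
  expect_equal(back$X, tab$X, ignore_attr = TRUE)
  expect_identical(nlevels(back$labels), 6L)
  expect_identical(as.character(back$labels), as.character(tab$labels))
})

test_that("the supplementary reader enforces shape and numeric content", {
  dir <- withr_local_tempdir()
  good <- matrix(seq_len(12) / 10, 3, 4)
  utils::write.table(good, file.path(dir, "a.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  bad <- good
  utils::write.table(bad[1:2, ], file.path(dir, "short.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  txt <- readLines(file.path(dir, "a.csv"))
  txt[2] <- sub("0.2", "oops", txt[2])
  writeLines(txt, file.path(dir, "nonnum.csv"))
  paths <- file.path(dir, c("a.csv", "short.csv"))
  expect_error(read_spectra_table(paths, labels = c("x", "y"), n_rows = 3,
                                  n_cols = 4),
               class = "hyperseed_format_error")
  err <- expect_error(
    read_spectra_table(file.path(dir, "nonnum.csv"), labels = "x",
                       n_rows = 3, n_cols = 4),
    class = "hyperseed_format_error")
  expect_match(conditionMessage(err), "nonnum.csv")
  # duplicate file for two classes: accepted with a warning
  expect_warning(
    dup <- read_spectra_table(rep(file.path(dir, "a.csv"), 2),
                              labels = c("x", "y"), n_rows = 3,
                              n_cols = 4),
    "more than one class")
  expect_identical(nrow(dup$X), 6L)
  expect_identical(nlevels(dup$labels), 2L)
})

test_that("ENVI cubes round-trip through every interleave", {
  set.seed(11)
  cube <- spectral_cube(array(runif(6 * 7 * 5), c(6, 7, 5)),
                        wavelengths = c(410, 450, 520, 600, 700))
  dir <- withr_local_tempdir()
  for (il in c("bsq", "bil", "bip")) {
    path <- file.path(dir, paste0("cube_", il, ".raw"))
    write_envi(cube, path, interleave = il)
    back <- read_envi(path)
    expect_equal(back$values, cube$values, info = il)
    expect_equal(back$wavelengths, cube$wavelengths)
  }
})
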