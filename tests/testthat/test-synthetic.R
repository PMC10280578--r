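test_that("class means differ only at informative bands and stay in range", {
  cfg <- synth_config(seed = 2)
  truth <- make_class_means(cfg)
  M <- truth$class_means
  expect_identical(dim(M), c(6L, 176L))
  expect_true(all(M >= 0 & M <= 1.2))
  outside <- setdiff(seq_len(176), truth$informative_idx)
  for (k in 2:6)
    expect_equal(M[k, outside], M[1, outside], tolerance = 1e-12)
  # some genuine difference inside the window
  expect_gt(max(abs(M[6, truth$window_idx] - M[1, truth$window_idx])), 0)
  # zero separation collapses all classes onto the base curve
  truth0 <- make_class_means(synth_config(class_sep = 0, seed = 2))
  expect_equal(truth0$class_means,
               matrix(truth0$class_means[1, ], 6, 176, byrow = TRUE))
})

test_that("sampling is exactly reproducible and noiseless rows equal their class mean", {
  cfg <- synth_config(seed = 3)
  d1 <- sample_dataset(cfg)
  d2 <- sample_dataset(cfg)
  expect_identical(d1$table$X, d2$table$X)
  expect_identical(levels(d1$table$labels),
                   sprintf("variety%d", 1:6))
  expect_identical(as.integer(table(d1$table$labels)), rep(60L, 6))
  clean <- sample_dataset(synth_config(gain_sd = 0, offset_sd = 0,
                                       noise_sd = 0, seed = 3))
  cls <- as.integer(clean$table$labels)
  expect_equal(clean$table$X, clean$truth$class_means[cls, ],
               ignore_attr = TRUE)
})

test_that("scatter correction removes most of the planted within-class variance", {
  # simulation oracle: the generator's gain/offset model is exactly the
  # distortion MSC fits, so MSC-corrected within-class variance must
  # collapse relative to the raw spectra
  ratios <- vapply(1:5, function(s) {
    tab <- sample_dataset(synth_config(seed = s))$table
    within_var <- function(X) {
      mean(vapply(levels(tab$labels), function(cl) {
        mean(apply(X[tab$labels == cl, ], 2, var))
      }, numeric(1)))
    }
    within_var(msc(tab$X)$X) / within_var(tab$X)
  }, numeric(1))
  expect_lt(mean(ratios), 0.25)
})

test_that("the supplementary writer emits six 60-row files plus a manifest that reads back", {
  tab <- sample_dataset(synth_config(seed = 4))$table
  dir <- file.path(tempdir(), "synth_supp")
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- write_supplementary_format(tab, dir)
  files <- yaml::read_yaml(manifest)$files
  expect_length(files, 6)
  expect_setequal(vapply(files, `[[`, "", "label"),
                  sprintf("variety%d", 1:6))
  first <- utils::read.csv(file.path(dir, files[[1]]$path), header = FALSE)
  expect_identical(dim(first), c(60L, 176L))
  back <- read_spectra_table(manifest)
  expect_equal(back$X, tab$X[order(tab$labels), , drop = FALSE],
               ignore_attr = TRUE)
})
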