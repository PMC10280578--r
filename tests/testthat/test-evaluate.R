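test_that("confusion matrices count with a fixed class order", {
  y <- c("a", "a", "b", "c")
  cm <- confusion(y, y, classes = c("a", "b", "c"))
  expect_equal(unclass(cm), diag(c(2, 1, 1)), ignore_attr = TRUE)
  cm2 <- confusion("a", "b", classes = c("a", "b"))
  expect_equal(as.numeric(cm2), c(0, 0, 1, 0))  # one off-diagonal count
  set.seed(31)
  yt <- sample(c("a", "b", "c"), 60, replace = TRUE)
  yp <- sample(c("a", "b", "c"), 60, replace = TRUE)
  cm3 <- confusion(yt, yp, classes = c("a", "b", "c"))
  expect_equal(as.numeric(rowSums(cm3)),
               as.numeric(table(factor(yt, c("a", "b", "c")))))
  expect_error(confusion(c("a", "z"), c("a", "a"), classes = c("a", "b")),
               class = "hyperseed_label_error")
})

test_that("kappa matches its closed form and its invariances", {
  expect_equal(kappa_statistic(diag(c(10, 20, 30))), 1)
  # oracle: p_o = 85/100, p_e = (50*55 + 50*45)/100^2 = 0.5
  cm <- matrix(c(45, 10, 5, 40), 2)
  expect_equal(kappa_statistic(cm), 0.70)
  expect_equal(precision_overall(cm), 0.85)
  # invariant to a simultaneous row/column permutation
  perm <- c(2, 1)
  expect_equal(kappa_statistic(cm[perm, perm]), kappa_statistic(cm))
  # degenerate marginals fall back to 0 with a warning
  expect_warning(k0 <- kappa_statistic(matrix(c(5, 0, 0, 0), 2)),
                 "undefined")
  expect_identical(k0, 0)
})

test_that("kappa of independent shuffled predictions is near zero", {
  # permutation oracle
  set.seed(33)
  y <- rep(1:4, each = 25)
  ks <- replicate(50, {
    kappa_statistic(confusion(y, sample(y), classes = 1:4))
  })
  expect_lt(abs(mean(ks)), 0.1)
})

test_that("repeat averaging reports per-repeat values and pooled counts", {
  # deterministic pipeline: every repeat identical, mean equals single
  fn <- function(seed) list(y_true = c("a", "a", "b", "b"),
                            y_pred = c("a", "b", "b", "b"))
  rep10 <- repeat_and_average(fn, n_repeats = 10, base_seed = 5)
  expect_identical(rep10$n_repeats, 10L)
  expect_equal(unique(rep10$per_repeat$precision), 0.75)
  expect_equal(rep10$precision, 0.75)
  expect_equal(sum(rep10$confusion), 40)
  expect_identical(rep10$per_repeat$seed, 5:14)
  # the mean lies within the per-repeat range for a stochastic pipeline
  fn2 <- function(seed) {
    hyperseed:::with_seed(seed, {
      y <- rep(c("a", "b"), each = 10)
      list(y_true = y, y_pred = sample(y))
    })
  }
  rep2 <- repeat_and_average(fn2, n_repeats = 6, base_seed = 1)
  expect_gte(rep2$precision, min(rep2$per_repeat$precision))
  expect_lte(rep2$precision, max(rep2$per_repeat$precision))
  # failures abort with the seed named
  bad <- function(seed) if (seed == 3) stop("boom") else fn(seed)
  err <- expect_error(repeat_and_average(bad, 5, base_seed = 1),
                      class = "hyperseed_repeat_failed")
  expect_match(conditionMessage(err), "seed 3")
})

test_that("macro precision averages per-class precision over predicted classes", {
  cm <- matrix(c(8, 2, 0, 10), 2)  # predicted-a: 10, predicted-b: 10
  expect_equal(precision_macro(cm), mean(c(8 / 10, 10 / 10)))
})
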