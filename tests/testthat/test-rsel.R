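test_that("a single full-dimension member reproduces the base classifier exactly", {
  tab <- small_table(seed = 7)
  part <- ks_split(tab$X, 50)
  Xtr <- tab$X[part$train_idx, ]
  ytr <- tab$labels[part$train_idx]
  Xte <- tab$X[part$test_idx, ]
  ens <- train_rsel(Xtr, ytr,
                    rsel_config(1, ncol(Xtr), weight_rule = "uniform",
                                seed = 1))
  lone <- train_base(base_classifier_spec("lda"), Xtr, ytr)
  expect_equal(predict_rsel(ens, Xte)$scores,
               predict_base(lone, Xte), ignore_attr = TRUE)
  expect_identical(as.character(predict_rsel(ens, Xte)$labels),
                   lone$classes[hyperseed:::row_argmax(predict_base(lone, Xte))])
})

test_that("member subspaces are reproducible, sized d, and weights sum to one", {
  tab <- small_table(seed = 8)
  cfg <- rsel_config(12, 9, seed = 5)
  e1 <- train_rsel(tab$X, tab$labels, cfg)
  e2 <- train_rsel(tab$X, tab$labels, cfg)
  idx1 <- lapply(e1$members, `[[`, "feature_idx")
  expect_identical(idx1, lapply(e2$members, `[[`, "feature_idx"))
  expect_true(all(vapply(idx1, function(i)
    length(i) == 9 && !anyDuplicated(i), TRUE)))
  expect_equal(sum(vapply(e1$members, `[[`, 1, "weight")), 1)
  # requesting more features than available is refused
  expect_error(train_rsel(tab$X, tab$labels,
                          rsel_config(3, ncol(tab$X) + 1, seed = 1)),
               class = "hyperseed_config_error")
})

test_that("weighted-average scores are convex combinations of member scores", {
  tab <- small_table(seed = 9)
  ens <- train_rsel(tab$X, tab$labels, rsel_config(8, 6, seed = 2))
  pred <- predict_rsel(ens, tab$X)
  expect_equal(rowSums(pred$scores), rep(1, nrow(tab$X)))
  member_scores <- lapply(ens$members, function(m)
    predict_base(m$clf, tab$X[, m$feature_idx, drop = FALSE]))
  lo <- Reduce(pmin, member_scores)
  hi <- Reduce(pmax, member_scores)
  expect_true(all(pred$scores >= lo - 1e-12))
  expect_true(all(pred$scores <= hi + 1e-12))
  # band-count mismatch is a shape error
  expect_error(predict_rsel(ens, tab$X[, 1:10]),
               class = "hyperseed_shape_error")
})

test_that("the ensemble beats a single random-subspace LDA on average", {
  # simulation oracle on generator defaults (reduced size for speed):
  # mean over seeds of ensemble accuracy vs one LDA on one random
  # d-subset
  accs <- vapply(1:10, function(s) {
    cfg <- synth_config(n_per_class = 25, seed = s)
    tab <- sample_dataset(cfg)$table
    pr <- hyperseed:::split_and_preprocess(tab, "msc", 110)
    ens <- train_rsel(pr$X_train, pr$y_train,
                      rsel_config(15, 40, seed = s))
    acc_ens <- mean(as.character(predict_rsel(ens, pr$X_test)$labels) ==
                      as.character(pr$y_test))
    single <- hyperseed:::with_seed(s, sort(sample(ncol(pr$X_train), 40)))
    clf <- train_base(base_classifier_spec("lda"),
                      pr$X_train[, single], pr$y_train)
    acc_one <- mean(clf$classes[hyperseed:::row_argmax(
      predict_base(clf, pr$X_test[, single]))] == as.character(pr$y_test))
    acc_ens - acc_one
  }, numeric(1))
  expect_gte(mean(accs), 0)
})

test_that("the scale grid has the requested layout and is seed-reproducible", {
  tab <- small_table(seed = 10)
  part <- ks_split(tab$X, 50)
  g1 <- grid_search_rsel(tab$X[part$train_idx, ], tab$labels[part$train_idx],
                         tab$X[part$test_idx, ], tab$labels[part$test_idx],
                         n_list = c(3, 5), d_list = c(5, 10, 15),
                         repeats = 1, seed = 4)
  expect_identical(dim(g1), c(2L, 3L))
  expect_true(all(g1 >= 0 & g1 <= 1))
  g2 <- grid_search_rsel(tab$X[part$train_idx, ], tab$labels[part$train_idx],
                         tab$X[part$test_idx, ], tab$labels[part$test_idx],
                         n_list = c(3, 5), d_list = c(5, 10, 15),
                         repeats = 1, seed = 4)
  expect_identical(g1, g2)
})
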