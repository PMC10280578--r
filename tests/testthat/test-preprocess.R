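test_that("SNV centres and scales each row by its own statistics", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  set.seed(5)
  X <- matrix(rnorm(8 * 30, mean = 3, sd = 2), 8)
  Z <- snv(X)
  expect_equal(rowMeans(Z), rep(0, 8))
  expect_equal(apply(Z, 1, sd), rep(1, 8))
  # idempotent up to the sd convention
  expect_equal(snv(Z), Z)
  # constant rows are rejected by name
  Xc <- X
  Xc[3, ] <- 0.5
  err <- expect_error(snv(Xc), class = "hyperseed_degenerate_spectrum")
  expect_match(conditionMessage(err), "row 3")
})

test_that("MSC leaves the reference unchanged and undoes planted gain/offset exactly", {
  set.seed(8)
  ref <- as.numeric(smooth(runif(50)))
  expect_equal(msc(rbind(ref), reference = ref)$X, rbind(ref),
               ignore_attr = TRUE)
  expect_equal(msc(rbind(2 + 3 * ref), reference = ref)$X, rbind(ref),
               ignore_attr = TRUE)
  # planted a_i + b_i * s with no noise: every corrected row equals s
  a <- runif(6, -0.5, 0.5)
  b <- runif(6, 0.5, 2)
  X <- outer(a, rep(1, 50)) + outer(b, ref)
  corrected <- msc(X, reference = ref)$X
  expect_equal(corrected, matrix(ref, 6, 50, byrow = TRUE),
               ignore_attr = TRUE)
  # default reference is the column mean and is returned for reuse
  fit <- msc(X)
  expect_equal(fit$reference, colMeans(X))
  # constant reference is unidentifiable
  expect_error(msc(X, reference = rep(1, 50)),
               class = "hyperseed_scatter_fit_degenerate")
})

test_that("the Savitzky-Golay first derivative is exact on polynomials up to its degree", {
  j <- 1:40
  const <- matrix(2.5, 3, 40)
  expect_equal(sg1(const), matrix(0, 3, 40))
  ramp <- rbind(5 * j)
  expect_equal(sg1(ramp), matrix(5, 1, 40))
  # oracle: analytic derivative of x_j = j^2 is 2j; a degree-2 fit
  # reproduces it exactly, edges included (asymmetric end windows)
  quad <- rbind(j^2)
  expect_equal(sg1(quad, window = 5, polyorder = 2), rbind(2 * j))
  # adding a constant does not change the derivative
  set.seed(9)
  X <- matrix(rnorm(4 * 40), 4)
  expect_equal(sg1(X + 7), sg1(X))
  # config validation
  expect_error(sg1(X, window = 4), class = "hyperseed_config_error")
  expect_error(sg1(X, window = 5, polyorder = 2, deriv = 3),
               class = "hyperseed_config_error")
})

test_that("the pretreatment dispatcher freezes its training state", {
  set.seed(10)
  Xtr <- matrix(runif(10 * 30), 10)
  Xte <- matrix(runif(4 * 30), 4)
  model <- preprocess_fit(Xtr, "msc")
  expect_equal(model$reference, colMeans(Xtr))
  # test rows are corrected against the training reference, not their own
  got <- preprocess_apply(model, Xte)
  expect_equal(got, msc(Xte, reference = colMeans(Xtr))$X)
  # the other methods pass through their row-wise definitions
  expect_equal(preprocess_apply(preprocess_fit(Xtr, "snv"), Xte),
               snv(Xte))
  expect_equal(preprocess_apply(preprocess_fit(Xtr, "none"), Xte), Xte)
  expect_equal(preprocess_apply(preprocess_fit(Xtr, "sg1"), Xte),
               sg1(Xte))
})
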