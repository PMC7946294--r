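test_that("z-scoring standardizes by training statistics only", {
  z <- zscore_fit_apply(cbind(c(1, 3)), cbind(2))
  expect_equal(as.vector(z$train), c(-1, 1))   # population SD = 1
  expect_equal(as.vector(z$test), 0)           # transformed with train stats
  # constant features map to zero, never NaN
  z2 <- zscore_fit_apply(cbind(c(2, 2, 2)), cbind(c(5, 2)))
  expect_true(all(z2$train == 0) && all(z2$test == 0))
  # test set uses train mean/SD, not its own
  z3 <- zscore_fit_apply(cbind(c(0, 2)), cbind(c(10, 12)))
  expect_equal(as.vector(z3$test), c(9, 11))
  expect_error(zscore_fit_apply(matrix(0, 0, 1), cbind(1)), "empty")
})

test_that("the linear SVM separates separable data and is deterministic", {
  x <- rbind(c(1, 1), c(-1, -1))
  y <- factor(c("a", "b"))
  for (cost in c(1, 2^20)) {
    fit <- train_linear_svm(x, y, cost)
    expect_equal(as.character(predict(fit, x)), c("a", "b"))
  }
  f1 <- train_linear_svm(x, y, 8)
  f2 <- train_linear_svm(x, y, 8)
  expect_identical(f1$w, f2$w)
  expect_error(train_linear_svm(x, factor(c("a", "a")), 1), "two classes")
})

test_that("the SVM stays finite and useful across the whole cost grid", {
  withr::with_seed(121, {
    x <- matrix(rnorm(40), 20, 2)
    x[1:10, ] <- x[1:10, ] + 1.5
    y <- factor(rep(c("w", "a"), each = 10), levels = c("w", "a"))
    for (cost in cost_grid_default()) {
      fit <- train_linear_svm(x, y, cost)
      expect_true(all(is.finite(fit$w)))
      expect_gt(mean(predict(fit, x) == y), 0.5)
    }
  })
})

test_that("held-out accuracy sits at chance when labels carry no signal", {
  withr::with_seed(122, {
    accs <- vapply(1:60, function(i) {
      x <- matrix(rnorm(24), 12, 2)
      y <- factor(rep(c("w", "a"), 6))
      fit <- train_linear_svm(x[1:10, ], y[1:10], 1)
      mean(predict(fit, x[11:12, , drop = FALSE]) == y[11:12])
    }, numeric(1))
    expect_lt(abs(mean(accs) - 0.5), 0.15)
  })
})

make_paired_data <- function(n_pairs, delta, seed, d = 3) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_pairs * d), 2 * n_pairs, d)
    lab <- rep(c("wake", "anesthesia"), n_pairs)
    x[lab == "wake", ] <- x[lab == "wake", ] + delta
    list(x = x, labels = factor(lab, levels = c("wake", "anesthesia")),
         pair = rep(seq_len(n_pairs), each = 2))
  })
}

test_that("nested pair-wise CV runs one outer fold per pair", {
  d <- make_paired_data(8, 2.5, seed = 123)
  cv <- nested_loo_pair_cv(d$x, d$labels, d$pair, cost_grid = c(0.01, 1))
  expect_length(cv$fold_accuracy, 8)   # 8 epoch-pairs -> 8 outer folds
  expect_length(cv$chosen_costs, 8)
  expect_equal(cv$accuracy, mean(cv$fold_accuracy))
  # a cleanly separated feature decodes perfectly
  expect_equal(cv$accuracy, 1.0)
  expect_error(nested_loo_pair_cv(d$x[1:4, ], d$labels[1:4], d$pair[1:4]),
               "at least 3 pairs")
  bad <- d$pair
  bad[2] <- 99
  expect_error(nested_loo_pair_cv(d$x, d$labels, bad), "each class")
})

test_that("inner-loop ties select the lowest cost", {
  # featureless data: every cost scores the same in the inner loop
  d <- make_paired_data(5, 0, seed = 124)
  d$x[] <- 0
  cv <- nested_loo_pair_cv(d$x, d$labels, d$pair,
                           cost_grid = cost_grid_default())
  expect_true(all(cv$chosen_costs == 2^-50))
})

test_that("held-out pairs never leak into cost selection", {
  d <- make_paired_data(6, 1.0, seed = 125)
  cv1 <- nested_loo_pair_cv(d$x, d$labels, d$pair, cost_grid = c(0.01, 1, 100))
  # corrupt the features of pair 4 only; the fold where it is held out must
  # still select the same cost (training never saw it)
  x2 <- d$x
  x2[d$pair == 4, ] <- 50
  cv2 <- nested_loo_pair_cv(x2, d$labels, d$pair, cost_grid = c(0.01, 1, 100))
  expect_equal(cv1$chosen_costs[4], cv2$chosen_costs[4])
})

test_that("study decoding yields one accuracy per channel set and unit", {
  study <- tiny_binary_study(n_subjects = 3, n_epochs = 4, n_channels = 3,
                             samples = 400)
  res <- run_study(study, k = 2, tau_samples = 2)
  acc <- decode_study(res, feature = "iis", mode = "within",
                      cost_grid = c(2^-10, 1))
  expect_equal(nrow(acc), choose(3, 2) * 3)    # sets x subjects
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 1))
  expect_true(all(acc$n_pairs == 4))
  accx <- decode_study(res, feature = "big_phi", mode = "across",
                       cost_grid = c(1))
  expect_equal(nrow(accx), choose(3, 2) * 4)   # sets x epochs
  expect_true(all(accx$n_pairs == 3))          # subjects pair across flies
  expect_error(decode_study(res, feature = "mechanism", mode = "within"),
               "supply `mechanism`")
})

test_that("mechanism-size aggregation averages the full census", {
  per <- tidyr::expand_grid(set_id = 1, unit = 1:2,
                            mechanism = mechanism_labels_test(3))
  per$accuracy <- seq_len(nrow(per)) / nrow(per)
  by_size <- aggregate_by_mechanism_size(per)
  expect_equal(nrow(by_size), 2 * 3)
  # size-2 rows average exactly the 3 two-channel mechanisms
  u1 <- per[per$unit == 1, ]
  expect_equal(by_size$accuracy[by_size$unit == 1 & by_size$size == 2],
               mean(u1$accuracy[nchar(u1$mechanism) == 2]))
  expect_error(aggregate_by_mechanism_size(per[-1, ]), "census")
})
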