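test_that("feedforward generator encodes the copy chain", {
  # perfect copy: node 2 follows node 1 exactly
  t1 <- make_feedforward_tpm(2, 1.0)
  s1_on <- bitwAnd(0:3, 1L) > 0
  expect_equal(t1[s1_on, 2], c(1, 1))
  expect_equal(t1[!s1_on, 2], c(0, 0))
  # fidelity 0.5: the copy carries no information
  t2 <- make_feedforward_tpm(2, 0.5)
  expect_true(all(t2[, 2] == 0.5))
  # construction passes the structural check
  expect_true(is_feedforward_tpm(make_feedforward_tpm(3, 0.9)))
  expect_error(make_feedforward_tpm(7, 0.9), "between 2 and 5")
  expect_error(make_feedforward_tpm(3, 0.3), "\\[0.5, 1\\]")
})

test_that("recurrent generator is seed-deterministic with a 0.5 floor", {
  expect_true(all(make_recurrent_tpm(4, 0, seed = 1) == 0.5))
  a <- make_recurrent_tpm(2, 1.3, seed = 9)
  b <- make_recurrent_tpm(2, 1.3, seed = 9)
  expect_identical(unclass(a)[, ], unclass(b)[, ])
  expect_false(identical(unclass(a)[, ],
                         unclass(make_recurrent_tpm(2, 1.3, seed = 10))[, ]))
  expect_error(make_recurrent_tpm(2, -1, seed = 1), ">= 0")
})

test_that("feedforward structure is detected and coupling destroys it", {
  for (seed in 101:104) {
    expect_true(is_feedforward_tpm(random_feedforward_tpm(4, seed)))
  }
  broken <- 0
  for (seed in 101:106) {
    if (!is_feedforward_tpm(make_recurrent_tpm(3, 2.5, seed = seed))) {
      broken <- broken + 1
    }
  }
  expect_gte(broken, 5)  # strong symmetric coupling is essentially never acyclic
})

test_that("sampled trajectories follow deterministic dynamics", {
  # one-node self-flip: alternates forever
  flip <- as_tpm(cbind(c(1, 0)))
  x <- sample_time_series(flip, 6, seed = 1)
  expect_true(all(abs(diff(as.vector(x))) == 1))
  # all-0.5: per-node on-fraction within 3 standard errors of 0.5
  t05 <- as_tpm(matrix(0.5, 4, 2))
  y <- sample_time_series(t05, 1e5, seed = 2)
  se <- 0.5 / sqrt(1e5)
  expect_true(all(abs(colMeans(y) - 0.5) < 3 * se))
  # determinism
  expect_identical(sample_time_series(flip, 10, seed = 3),
                   sample_time_series(flip, 10, seed = 3))
})

test_that("sampling and re-estimation recover the generating TPM", {
  gen <- make_recurrent_tpm(3, 1.5, seed = 5)
  x <- sample_time_series(gen, 1e5, seed = 6)
  est <- estimate_tpm(x, tau_samples = 1)
  expect_true(!any(attr(est, "unobserved")))
  expect_lt(max(abs(est - gen)), 0.02)
})

test_that("study configuration validates the coupling contrast", {
  cfg <- synthetic_study_config()
  expect_equal(cfg$n_subjects, 13L)
  expect_equal(cfg$n_epochs_per_condition, 8L)
  expect_equal(cfg$n_channels, 15L)
  expect_equal(cfg$samples_per_epoch, 2250L)
  expect_gt(cfg$coupling_wake, cfg$coupling_anesthesia)
  expect_error(synthetic_study_config(coupling_wake = 0.1,
                                      coupling_anesthesia = 0.2),
               "exceed")
  # equality is allowed: it is the degenerate no-contrast control
  expect_s3_class(synthetic_study_config(coupling_wake = 0.2,
                                         coupling_anesthesia = 0.2),
                  "iis_study_config")
})

test_that("pseudo-LFP studies have the configured dimensions and reproduce", {
  cfg <- synthetic_study_config(n_subjects = 2, n_epochs_per_condition = 3,
                                n_channels = 4, samples_per_epoch = 500,
                                seed = 11)
  study <- generate_pseudo_lfp(cfg)
  expect_equal(nrow(study), 2 * 2 * 3)
  expect_true(all(vapply(study$lfp, nrow, integer(1)) == 500))
  expect_true(all(vapply(study$lfp, ncol, integer(1)) == 4))
  expect_equal(levels(study$condition), c("wake", "anesthesia"))
  # bit-identical regeneration under the same seed
  again <- generate_pseudo_lfp(cfg)
  expect_identical(study$lfp, again$lfp)
  # different seed, different data
  other <- generate_pseudo_lfp(synthetic_study_config(
    n_subjects = 2, n_epochs_per_condition = 3, n_channels = 4,
    samples_per_epoch = 500, seed = 12))
  expect_false(identical(study$lfp[[1]], other$lfp[[1]]))
  # epochs are distinct draws
  expect_false(identical(study$lfp[[1]], study$lfp[[2]]))
})

test_that("pseudo-LFP traces look like stationary oscillatory signals", {
  cfg <- synthetic_study_config(n_subjects = 1, n_epochs_per_condition = 1,
                                n_channels = 3, samples_per_epoch = 2250,
                                seed = 21)
  x <- generate_pseudo_lfp(cfg)$lfp[[1]]
  expect_true(all(is.finite(x)))
  expect_true(all(apply(x, 2, sd) > 0))
  # autocorrelated at the working lag but far from a random walk
  r4 <- cor(x[-(1:4), 1], x[seq_len(nrow(x) - 4), 1])
  expect_gt(r4, 0.1)
  expect_lt(r4, 0.95)
})
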