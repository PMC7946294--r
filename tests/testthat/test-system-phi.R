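test_that("unidirectional cuts enumerate all ordered bipartitions", {
  expect_equal(nrow(enumerate_cuts(2)), 2)
  expect_equal(nrow(enumerate_cuts(4)), 14)
  expect_error(enumerate_cuts(1), "at least 2")
  cuts <- enumerate_cuts(3)
  for (i in seq_len(nrow(cuts))) {
    expect_identical(sort(c(cuts$from[[i]], cuts$to[[i]])), 1:3)
    expect_gt(length(cuts$from[[i]]), 0)
    expect_gt(length(cuts$to[[i]]), 0)
  }
})

test_that("cutting a non-existent connection leaves the TPM unchanged", {
  chain <- make_feedforward_tpm(3, 0.85)
  # nothing feeds back from node 3, so cutting {3} -> {1,2} changes nothing
  cut <- apply_cut(chain, 3)
  expect_equal(unclass(cut)[, ], unclass(chain)[, ], tolerance = 1e-15)
  # and the cause-effect structure is identical too
  ces_f <- compute_ces(chain, c(1, 0, 1))
  ces_c <- compute_ces(cut, c(1, 0, 1))
  expect_equal(ces_f$concepts$phi, ces_c$concepts$phi, tolerance = 1e-12)
  expect_equal(ces_distance(ces_f, ces_c), 0, tolerance = 1e-12)
})

test_that("noised cuts are idempotent and match the averaging oracle", {
  tpm <- random_tpm(3, 71)
  for (from in list(1, 2, c(1, 3), c(2, 3))) {
    once <- apply_cut(as_tpm(tpm), from)
    twice <- apply_cut(once, from)
    expect_equal(unclass(once)[, ], unclass(twice)[, ], tolerance = 1e-14)
    expect_equal(unclass(once)[, ], or_apply_cut(tpm, from), tolerance = 1e-12)
  }
  expect_error(apply_cut(as_tpm(tpm), 1:3), "proper subset")
})

test_that("identical structures are at distance zero", {
  tpm <- random_tpm(3, 72)
  ces <- compute_ces(tpm, c(0, 1, 1))
  expect_equal(ces_distance(ces, ces), 0, tolerance = 1e-12)
})

test_that("against an all-zero cut the distance collapses to the residual sum", {
  tpm <- as_tpm(random_tpm(2, 73))
  state <- c(1, 0)
  full <- compute_ces(tpm, state)
  flat <- compute_ces(as_tpm(matrix(0.5, 4, 2)), state)  # every phi = 0
  expect_true(all(flat$concepts$phi == 0))
  want <- 0
  unif <- rep(0.25, 4)
  for (mask in 1:3) {
    d <- full$details[[mask]]
    if (d$phi > 0) {
      eff_big <- marginals_to_rep_test(d$effect$marginals)
      want <- want + d$phi * (emd(d$cause$repertoire_full, unif) +
                                emd(eff_big, full$unconstrained_effect))
    }
  }
  expect_equal(ces_distance(full, flat), want, tolerance = 1e-12)
})

test_that("system phi agrees between the R formula and the engine search", {
  tpm <- as_tpm(random_tpm(3, 74))
  state <- c(1, 1, 0)
  res <- compute_big_phi(tpm, state)
  # recompute each cut's distance through the R-level structure comparison
  full <- compute_ces(tpm, state)
  dists <- vapply(seq_len(6), function(i) {
    ces_distance(full, compute_ces(apply_cut(tpm, I(i)), state))
  }, numeric(1))
  expect_equal(res$big_phi, min(dists), tolerance = 1e-10)
  finite <- !is.na(res$cut_distances)
  expect_equal(res$cut_distances[finite], dists[finite], tolerance = 1e-10)
  # the reported minimal cut attains the minimum
  cut_mask <- sum(2^(res$minimal_cut$from - 1))
  expect_equal(dists[cut_mask], min(dists), tolerance = 1e-10)
})

test_that("feedforward systems generate zero system-level integrated information", {
  for (seed in 81:84) {
    tpm <- random_feedforward_tpm(3, seed)
    expect_true(is_feedforward_tpm(tpm))
    res <- system_phi_by_state(tpm)
    expect_lt(max(abs(res$big_phi)), 1e-9)
  }
})

test_that("independent subsystems compose to zero system phi", {
  tpm <- independent_pairs_tpm(seed = 5)
  res <- system_phi_by_state(tpm)
  expect_lt(max(abs(res$big_phi)), 1e-9)
})

test_that("system phi matches the brute-force oracle on random systems", {
  tpm <- random_tpm(2, 85)
  expect_equal(system_phi_by_state(as_tpm(tpm))$big_phi, or_big_phi_all(tpm),
               tolerance = 1e-8)
  tpm3 <- random_tpm(3, 86)
  got <- system_phi_by_state(as_tpm(tpm3))$big_phi
  expect_equal(got, or_big_phi_all(tpm3), tolerance = 1e-8)
  expect_gt(max(got), 0)   # a dense random recurrent system integrates
})

test_that("state-averaged system phi grows with coupling strength", {
  weak <- make_recurrent_tpm(4, 0.2, seed = 7)
  strong <- make_recurrent_tpm(4, 2.0, seed = 7)
  expect_gt(mean(system_phi_by_state(strong)$big_phi),
            mean(system_phi_by_state(weak)$big_phi))
})
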