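test_that("a repertoire that factorizes across a partition is reducible", {
  # two independent self-coupled nodes: A' depends only on A, B' only on B,
  # so every mechanism/purview factorizes and phi vanishes
  s1 <- bitwAnd(0:3, 1L) > 0
  s2 <- bitwAnd(0:3, 2L) > 0
  tpm <- as_tpm(cbind(ifelse(s1, 0.9, 0.2), ifelse(s2, 0.7, 0.4)))
  for (dir in c("cause", "effect")) {
    expect_equal(phi_mip(tpm, c(1, 2), c(1, 0), c(1, 2), dir)$phi, 0,
                 tolerance = 1e-12)
  }
})

test_that("the minimal disconnection severs the weakest link", {
  # node 1 drives itself strongly but node 2 only weakly; for mechanism {1}
  # over purview {1,2} the cheapest disconnection cuts the 1 -> 2 influence
  s1 <- bitwAnd(0:3, 1L) > 0
  tpm <- as_tpm(cbind(ifelse(s1, 0.9, 0.1), ifelse(s1, 0.55, 0.45)))
  res <- phi_mip(tpm, 1, 1, c(1, 2), "effect")
  expect_gt(res$phi, 0)
  # the severed part pairs the mechanism with purview {1}, noising 1 -> 2
  parts <- list(res$partition$part1, res$partition$part2)
  cut_to_2 <- any(vapply(parts, function(p) {
    length(p$mechanism) == 0 && identical(p$purview, 2L)
  }, logical(1)))
  expect_true(cut_to_2)
})

test_that("phi over the minimum-information partition matches the oracle", {
  for (seed in c(61, 62)) {
    tpm <- random_tpm(2, seed)
    for (mech in or_all_purviews(2)) {
      msl_all <- or_states(length(mech))
      for (r in seq_len(nrow(msl_all))) {
        for (pv in or_all_purviews(2)) {
          for (dir in c("cause", "effect")) {
            got <- phi_mip(tpm, mech, msl_all[r, ], pv, dir)$phi
            want <- or_phi_mip(tpm, mech, msl_all[r, ], pv, dir == "cause")
            expect_equal(got, want, tolerance = 1e-10)
          }
        }
      }
    }
  }
  # one 3-node system, sampled mechanism-states
  tpm <- random_tpm(3, 63)
  withr::with_seed(64, {
    for (rep in 1:10) {
      mech <- sort(sample(3, sample(3, 1)))
      ms <- sample(0:1, length(mech), replace = TRUE)
      pv <- sort(sample(3, sample(3, 1)))
      dir <- sample(c("cause", "effect"), 1)
      expect_equal(phi_mip(tpm, mech, ms, pv, dir)$phi,
                   or_phi_mip(tpm, mech, ms, pv, dir == "cause"),
                   tolerance = 1e-10)
    }
  })
})

test_that("a source mechanism specifies no causes and a sink no effects", {
  chain <- make_feedforward_tpm(3, 0.9)
  # node 1 takes no inputs from the system: zero cause information
  cc <- core_repertoire(chain, 1, 1, "cause")
  expect_equal(cc$phi, 0, tolerance = 1e-12)
  for (pv in or_all_purviews(3)) {
    expect_equal(phi_mip(chain, 1, 1, pv, "cause")$phi, 0, tolerance = 1e-12)
  }
  # node 3 feeds nothing: zero effect information
  ce <- core_repertoire(chain, 3, 1, "effect")
  expect_equal(ce$phi, 0, tolerance = 1e-12)
})

test_that("core purview search agrees with the oracle scan", {
  for (seed in c(65, 66)) {
    tpm <- random_tpm(3, seed)
    withr::with_seed(seed + 100, {
      for (rep in 1:6) {
        mech <- sort(sample(3, sample(3, 1)))
        ms <- sample(0:1, length(mech), replace = TRUE)
        for (dir in c("cause", "effect")) {
          got <- core_repertoire(tpm, mech, ms, dir)
          want <- or_core(tpm, mech, ms, dir == "cause")
          expect_equal(got$phi, want$phi, tolerance = 1e-10)
          expect_identical(got$purview, want$purview)
        }
      }
    })
  }
})

test_that("a concept's phi is the minimum of its two sides", {
  tpm <- random_tpm(3, 67)
  cn <- concept(tpm, c(1, 3), c(1, 0, 1))
  expect_equal(cn$phi, min(cn$core_cause$phi, cn$core_effect$phi))
  # all-0.5 system: every mechanism has zero phi
  t05 <- as_tpm(matrix(0.5, 8, 3))
  for (mech in or_all_purviews(3)) {
    expect_equal(concept(t05, mech, c(0, 1, 0))$phi, 0, tolerance = 1e-12)
  }
})

test_that("the cause-effect structure holds one concept per mechanism", {
  tpm <- random_tpm(4, 68)
  ces <- compute_ces(tpm, c(0, 1, 1, 0))
  expect_equal(nrow(ces$concepts), 15)
  expect_equal(as.vector(table(ces$concepts$size)), c(4, 6, 4, 1))
  expect_identical(ces$concepts$mechanism[1:5], c("1", "2", "12", "3", "13"))
  expect_true(all(ces$concepts$phi >= 0))
  expect_equal(ces$concepts$phi,
               pmin(ces$concepts$phi_cause, ces$concepts$phi_effect))
})
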