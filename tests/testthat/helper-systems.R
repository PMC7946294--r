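# small constructed systems shared across tests

# permute the node labels of a state-by-node TPM: node j of the output is
# node perm[j] of the input
permute_tpm_nodes <- function(tpm, perm) {
  n <- ncol(tpm)
  ns <- 2^n
  out <- matrix(0, ns, n)
  for (s in 0:(ns - 1)) {
    bits <- as.integer(bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L))
    src_bits <- integer(n)
    src_bits[perm] <- bits              # input node perm[j] carries bit j
    src_row <- sum(src_bits * 2^(0:(n - 1))) + 1L
    out[s + 1, ] <- tpm[src_row, perm]
  }
  out
}

# deterministic 2-node swap: A' = B, B' = A
swap_tpm <- function() {
  as_tpm(cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)))
}

# two independent recurrent pairs composed into one 4-node system
independent_pairs_tpm <- function(seed = 1, coupling = 2) {
  p <- make_recurrent_tpm(2, coupling, seed = seed)
  comp <- matrix(0, 16, 4)
  for (s in 0:15) {
    b <- state_from_index(s, 4)
    comp[s + 1, 1:2] <- p[state_index(b[1:2]) + 1, ]
    comp[s + 1, 3:4] <- p[state_index(b[3:4]) + 1, ]
  }
  as_tpm(comp)
}

# random feedforward system: a chain with random fidelity under a random
# node relabelling
random_feedforward_tpm <- function(n, seed) {
  withr::with_seed(seed, {
    fid <- runif(1, 0.6, 1)
    perm <- sample(n)
    as_tpm(permute_tpm_nodes(make_feedforward_tpm(n, fid), perm))
  })
}

# canonical mechanism labels (mask order) without touching package internals
mechanism_labels_test <- function(n) {
  vapply(seq_len(2^n - 1), function(m) {
    paste(which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0), collapse = "")
  }, character(1))
}

# expand per-node on-marginals into the factorized joint distribution
marginals_to_rep_test <- function(m) {
  st <- or_states(length(m))
  apply(st, 1, function(z) prod(ifelse(z == 1, m, 1 - m)))
}

# small pre-binarized study tibble for pipeline tests
tiny_binary_study <- function(n_subjects = 2, n_epochs = 2, n_channels = 4,
                              samples = 400, seed = 42) {
  grid <- tidyr::expand_grid(
    subject = seq_len(n_subjects),
    condition = factor(c("wake", "anesthesia"), levels = c("wake", "anesthesia")),
    epoch = seq_len(n_epochs)
  )
  tpm <- make_recurrent_tpm(n_channels, 1.2, seed = seed)
  grid$bin <- lapply(seq_len(nrow(grid)), function(i) {
    sample_time_series(tpm, samples, seed = seed + i)
  })
  grid
}
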