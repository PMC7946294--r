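#' Feedforward chain TPM
#'
#' Ground-truth binary system with purely feedforward structure: node 1
#' switches on with probability 0.5 independently of everything, and each
#' node `i + 1` copies node `i`'s current state with probability
#' `copy_fidelity`. Feedforward systems generate zero system-level
#' integrated information, because severing the (non-existent) feedback
#' direction leaves the dynamics untouched.
#'
#' @param n_nodes Number of nodes, 2 to 5.
#' @param copy_fidelity Probability in `[0.5, 1]` that the copy succeeds;
#'   0.5 carries no information, 1 is a deterministic copy.
#' @return An `iit_tpm`.
#' @examples
#' make_feedforward_tpm(3, 0.9)
#' @export
make_feedforward_tpm <- function(n_nodes, copy_fidelity) {
  if (n_nodes < 2 || n_nodes > 5) stop("`n_nodes` must be between 2 and 5")
  if (copy_fidelity < 0.5 || copy_fidelity > 1) {
    stop("`copy_fidelity` must lie in [0.5, 1]")
  }
  ns <- 2^n_nodes
  probs <- matrix(0.5, ns, n_nodes)
  for (j in 2:n_nodes) {
    src_on <- bitwAnd(0:(ns - 1), 2^(j - 2)) > 0
    probs[, j] <- ifelse(src_on, copy_fidelity, 1 - copy_fidelity)
  }
  as_tpm(probs)
}

#' Random recurrent TPM with logistic coupling
#'
#' Each node's on-probability is a logistic function of a weighted sum of
#' all nodes' current states (coded -1/+1), with symmetric Gaussian random
#' weights scaled by `coupling`. Zero coupling gives the maximally
#' uninformative all-0.5 matrix; growing coupling produces increasingly
#' deterministic, recurrent dynamics. The logistic link guarantees valid
#' probabilities at any coupling.
#'
#' @param n_nodes Number of nodes.
#' @param coupling Nonnegative coupling strength.
#' @param seed Integer seed for the random weights; fixed seed, fixed matrix.
#' @return An `iit_tpm`.
#' @export
make_recurrent_tpm <- function(n_nodes, coupling, seed) {
  if (coupling < 0) stop("`coupling` must be >= 0")
  w <- withr::with_seed(as.integer(seed), {
    a <- matrix(rnorm(n_nodes^2), n_nodes, n_nodes)
    (a + t(a)) / sqrt(2)
  })
  ns <- 2^n_nodes
  states <- t(vapply(0:(ns - 1), state_from_index, integer(n_nodes),
                     n_nodes = n_nodes))
  signs <- 2 * states - 1                       # ns x n in {-1, +1}
  probs <- stats::plogis(coupling * (signs %*% w))
  as_tpm(probs)
}

#' Sample a binary Markov chain from a TPM
#'
#' Draws a trajectory from the system: the state at `t + 1` is drawn
#' per-node independently from the TPM row of the state at `t` (the
#' conditional-independence assumption — no instantaneous interactions).
#'
#' @param tpm State-by-node TPM.
#' @param n_samples Number of samples (>= 1), including the initial state.
#' @param seed Integer seed.
#' @param init Optional 0/1 initial state; default drawn uniformly.
#' @return Binary matrix, `n_samples` by `n` nodes.
#' @export
sample_time_series <- function(tpm, n_samples, seed, init = NULL) {
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  n <- ncol(tpm)
  withr::with_seed(as.integer(seed), {
    out <- matrix(0L, n_samples, n)
    state <- if (is.null(init)) {
      as.integer(runif(n) < 0.5)
    } else {
      as.integer(init)
    }
    out[1, ] <- state
    if (n_samples > 1) {
      u <- matrix(runif((n_samples - 1) * n), n_samples - 1, n)
      pow <- 2^(seq_len(n) - 1L)
      for (t in 2:n_samples) {
        row <- sum(state * pow) + 1L
        state <- as.integer(u[t - 1, ] < tpm[row, ])
        out[t, ] <- state
      }
    }
    out
  })
}

#' Check the feedforward structural invariant of a TPM
#'
#' A system is feedforward if some node ordering exists under which no
#' node's next-state probability depends on the current state of any node
#' later in the ordering (testable as invariance of TPM columns to flips of
#' later-node bits). Searches all orderings; intended for small systems.
#'
#' @param tpm State-by-node TPM (n <= 6).
#' @param tol Numeric tolerance for column invariance.
#' @return Logical.
#' @export
is_feedforward_tpm <- function(tpm, tol = 1e-12) {
  n <- ncol(tpm)
  if (n > 6) stop("feedforward check supports n <= 6")
  # depends[j, i] = TRUE if column j reacts to flips of node i's bit
  depends <- matrix(FALSE, n, n)
  ns <- 2^n
  for (i in seq_len(n)) {
    flip <- bitwXor(0:(ns - 1), 2^(i - 1L)) + 1L
    for (j in seq_len(n)) {
      depends[j, i] <- any(abs(tpm[, j] - tpm[flip, j]) > tol)
    }
  }
  # feedforward <=> dependency graph (i -> j if j depends on i, i != j) is
  # acyclic; self-dependence is allowed. Topological-sort check.
  g <- depends
  diag(g) <- FALSE
  remaining <- seq_len(n)
  while (length(remaining)) {
    # a node no remaining node depends on may go last
    sink <- NULL
    for (j in remaining) {
      if (!any(g[setdiff(remaining, j), j])) { sink <- j; break }
    }
    if (is.null(sink)) return(FALSE)
    remaining <- setdiff(remaining, sink)
  }
  TRUE
}

#' Configuration of a synthetic two-condition study
#'
#' Mirrors the dimensions of the fly study the pipeline is designed around:
#' 13 subjects, 2 conditions (wake / anesthesia), 8 epochs per condition of
#' 2250 samples at 1000 Hz over 15 channels. Cross-channel coupling is
#' strong in wake and weakened under anesthesia, the generative analogue of
#' anesthesia preferentially disrupting global communication.
#'
#' @param n_subjects,n_epochs_per_condition,n_channels,samples_per_epoch
#'   Study dimensions.
#' @param sampling_rate Sampling rate in Hz.
#' @param coupling_wake,coupling_anesthesia Dimensionless cross-channel
#'   coupling strengths; anesthesia must not exceed wake (equality gives the
#'   degenerate no-contrast control study).
#' @param seed Integer master seed; fans out to per-subject/epoch substreams
#'   via a counter scheme.
#' @return A list of class `iis_study_config`.
#' @export
synthetic_study_config <- function(n_subjects = 13,
                                   n_epochs_per_condition = 8,
                                   n_channels = 15,
                                   samples_per_epoch = 2250,
                                   sampling_rate = 1000,
                                   coupling_wake = 0.35,
                                   coupling_anesthesia = 0.05,
                                   seed = 1) {
  if (coupling_anesthesia > coupling_wake) {
    stop("`coupling_anesthesia` must not exceed `coupling_wake`")
  }
  if (min(n_subjects, n_epochs_per_condition, n_channels,
          samples_per_epoch) < 1) {
    stop("study dimensions must be positive")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_epochs_per_condition = as.integer(n_epochs_per_condition),
                 n_channels = as.integer(n_channels),
                 samples_per_epoch = as.integer(samples_per_epoch),
                 sampling_rate = sampling_rate,
                 coupling_wake = coupling_wake,
                 coupling_anesthesia = coupling_anesthesia,
                 seed = as.integer(seed)),
            class = "iis_study_config")
}

# deterministic substream seed; keeps every derived seed below 2^31
substream_seed <- function(seed, counter) {
  (abs(seed) %% 65011L) * 33013L + counter %% 33013L
}

#' Generate a pseudo-LFP study
#'
#' Surrogate continuous recordings standing in for multichannel local field
#' potentials: each channel is a second-order autoregressive process with
#' Gaussian innovations (oscillatory, autocorrelated traces), coupled across
#' channels through a subject-specific random weight matrix applied to the
#' previous sample. The coupling strength is `coupling_wake` in wake epochs
#' and `coupling_anesthesia` in anesthesia epochs; all cross-channel weights
#' are scaled by the one condition factor. Epochs are generated
#' independently from per-epoch substreams of the master seed.
#'
#' @param config An [synthetic_study_config()] object.
#' @return A tibble with one row per subject x condition x epoch and columns
#'   `subject`, `condition` (factor wake/anesthesia), `epoch`, `lfp` (list of
#'   `samples_per_epoch` x `n_channels` matrices) and `seed` (the substream
#'   seed used).
#' @export
generate_pseudo_lfp <- function(config) {
  stopifnot(inherits(config, "iis_study_config"))
  nch <- config$n_channels
  ar1 <- 1.7
  ar2 <- -0.8
  grid <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    condition = factor(c("wake", "anesthesia"), levels = c("wake", "anesthesia")),
    epoch = seq_len(config$n_epochs_per_condition)
  )
  # subject-specific coupling topology, shared between conditions
  wmats <- lapply(seq_len(config$n_subjects), function(s) {
    withr::with_seed(substream_seed(config$seed, 1000L + s), {
      w <- matrix(rnorm(nch^2), nch, nch)
      diag(w) <- 0
      w <- (w + t(w)) / 2              # bidirectional coupling
      if (nch > 1) w / max(abs(eigen(w, only.values = TRUE)$values)) else w * 0
    })
  })
  counter <- 0L
  lfp <- vector("list", nrow(grid))
  sseed <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    counter <- counter + 1L
    sub <- grid$subject[r]
    cpl <- if (grid$condition[r] == "wake") config$coupling_wake else config$coupling_anesthesia
    sseed[r] <- substream_seed(config$seed, counter)
    lfp[[r]] <- withr::with_seed(sseed[r], {
      ar2_coupled(config$samples_per_epoch, nch, ar1, ar2,
                  cpl * 0.1 * wmats[[sub]])
    })
  }
  out <- grid
  out$lfp <- lfp
  out$seed <- sseed
  out
}

# coupled AR(2): x_t = ar1 x_{t-1} + ar2 x_{t-2} + C x_{t-1} + eps, burn-in
# discarded; innovations standard normal
ar2_coupled <- function(nsamp, nch, ar1, ar2, cmat) {
  burn <- 200L
  total <- nsamp + burn
  x <- matrix(0, total, nch)
  eps <- matrix(rnorm(total * nch), total, nch)
  a <- diag(ar1, nch) + cmat
  x[1, ] <- eps[1, ]
  x[2, ] <- eps[2, ]
  for (t in 3:total) {
    x[t, ] <- as.vector(a %*% x[t - 1, ]) + ar2 * x[t - 2, ] + eps[t, ]
  }
  x[(burn + 1):total, , drop = FALSE]
}
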