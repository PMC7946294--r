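#' Construct a state-by-node transition probability matrix
#'
#' A state-by-node TPM has `2^n` rows (the current system state, little-endian
#' per [state_index()]) and `n` columns giving each node's probability of
#' being 'on' at `t + tau`. Nodes are conditionally independent given the
#' current state, so the full `2^n x 2^n` state-by-state matrix is the product
#' of per-node Bernoullis and can be derived on demand.
#'
#' @param probs Numeric matrix, `2^n` rows by `n` columns, entries in `[0, 1]`.
#' @param tau_samples Lag (in samples) at which the transitions were taken.
#' @param unobserved Logical vector over the `2^n` states marking rows that
#'   were never observed and hold the maximum-entropy fill of 0.5.
#' @param counts Integer vector of per-state occurrence counts (states counted
#'   as the time-`t` end of a transition), or `NULL` when the matrix is
#'   specified analytically.
#' @return An object of class `iit_tpm`: the matrix with metadata attributes
#'   `tau_samples`, `state_order` (`"little-endian"`), `unobserved`, `counts`.
#' @export
as_tpm <- function(probs, tau_samples = 1L, unobserved = NULL, counts = NULL) {
  probs <- as.matrix(probs)
  n <- ncol(probs)
  if (nrow(probs) != 2^n) {
    stop("a state-by-node TPM needs 2^n rows for n columns; got ",
         nrow(probs), " x ", n)
  }
  if (any(probs < 0 | probs > 1 | is.na(probs))) {
    stop("TPM entries must lie in [0, 1]")
  }
  if (is.null(unobserved)) unobserved <- rep(FALSE, 2^n)
  structure(probs,
            tau_samples = as.integer(tau_samples),
            state_order = "little-endian",
            unobserved = unobserved,
            counts = counts,
            class = c("iit_tpm", "matrix", "array"))
}

#' @export
print.iit_tpm <- function(x, ...) {
  n <- ncol(x)
  cat("State-by-node TPM:", n, "nodes,", nrow(x), "states (little-endian),",
      "tau =", attr(x, "tau_samples"), "samples\n")
  m <- unclass(x)
  attributes(m) <- attributes(m)["dim"]
  rownames(m) <- vapply(0:(2^n - 1), function(s)
    paste(rev(state_from_index(s, n)), collapse = ""), character(1))
  colnames(m) <- paste0("n", seq_len(n))
  print(round(m, 4), ...)
  if (any(attr(x, "unobserved"))) {
    cat(sum(attr(x, "unobserved")), "state(s) unobserved (max-entropy fill)\n")
  }
  invisible(x)
}

#' Number of nodes of a TPM
#' @param tpm An `iit_tpm` (or plain `2^n x n` matrix).
#' @return Integer node count.
#' @export
n_nodes <- function(tpm) ncol(tpm)

#' Estimate a state-by-node TPM from a binarized time series
#'
#' Counts, at every valid time point `t` in `1 .. T - tau` (overlapping
#' transitions, never across epoch boundaries), the system state over the
#' selected nodes at `t` and each node's state at `t + tau`, and converts the
#' counts to empirical conditional probabilities: the probability of a node
#' being 'on' at `t + tau` given the system state at `t`. States never
#' observed at time `t` are filled with 0.5 per node (the maximum-entropy
#' fill) and flagged in the `unobserved` attribute; downstream state-weighted
#' averages give them zero weight.
#'
#' @param series Binary matrix (samples by channels), e.g. from
#'   [binarize_median()].
#' @param nodes Channel columns to use, in ascending order (default: all).
#' @param tau_samples Positive integer lag in samples. The study default is 4
#'   samples at 1000 Hz (4 ms); 2 and 6 samples support the lag sweep.
#' @return An `iit_tpm` whose `counts` attribute holds the per-state
#'   occurrence counts (a [state_counts()] vector).
#' @examples
#' x <- cbind(rep(c(0, 1), 50))            # one node, alternating
#' estimate_tpm(x, tau_samples = 1)
#' @export
estimate_tpm <- function(series, nodes = NULL, tau_samples = 1L) {
  series <- as.matrix(series)
  if (is.null(nodes)) nodes <- seq_len(ncol(series))
  nodes <- as.integer(nodes)
  if (anyDuplicated(nodes)) stop("`nodes` must be distinct")
  tau_samples <- as.integer(tau_samples)
  if (tau_samples < 1L) stop("`tau_samples` must be >= 1")
  sub <- series[, nodes, drop = FALSE]
  if (!all(sub %in% c(0L, 1L))) stop("`series` must be binary (0/1)")
  tt <- nrow(sub)
  if (tt <= tau_samples) {
    stop("series has no transitions at lag ", tau_samples,
         " (length ", tt, ")")
  }
  k <- length(nodes)
  ns <- 2^k
  idx <- as.vector(sub[seq_len(tt - tau_samples), , drop = FALSE] %*%
                     2^(seq_len(k) - 1L)) + 1L
  nxt <- sub[(tau_samples + 1L):tt, , drop = FALSE]
  counts <- tabulate(idx, nbins = ns)
  on_counts <- matrix(0, ns, k)
  agg <- rowsum(nxt, group = idx)
  on_counts[as.integer(rownames(agg)), ] <- agg
  probs <- matrix(0.5, ns, k)
  obs <- counts > 0L
  probs[obs, ] <- on_counts[obs, , drop = FALSE] / counts[obs]
  as_tpm(probs, tau_samples = tau_samples, unobserved = !obs,
         counts = as.integer(counts))
}

#' Per-state occurrence counts of an estimated TPM
#'
#' @param tpm An `iit_tpm` produced by [estimate_tpm()].
#' @return Integer vector over the `2^n` states; sums to the number of counted
#'   transitions.
#' @export
state_counts <- function(tpm) {
  counts <- attr(tpm, "counts")
  if (is.null(counts)) stop("this TPM carries no state counts")
  counts
}

#' Expand a state-by-node TPM to the full state-by-state matrix
#'
#' Uses the conditional-independence assumption: the joint transition
#' probability is the product of per-node Bernoulli probabilities.
#'
#' @param tpm An `iit_tpm` or plain state-by-node matrix.
#' @return A `2^n x 2^n` matrix; rows current state, columns next state.
#' @export
state_by_state <- function(tpm) {
  n <- ncol(tpm)
  ns <- 2^n
  out <- matrix(1, ns, ns)
  for (s2 in 0:(ns - 1)) {
    bits <- state_from_index(s2, n)
    for (j in seq_len(n)) {
      out[, s2 + 1] <- out[, s2 + 1] *
        (if (bits[j] == 1) tpm[, j] else 1 - tpm[, j])
    }
  }
  out
}
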