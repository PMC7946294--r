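#' Earth mover's distance between repertoires
#'
#' Exact earth mover's distance between two probability distributions over
#' the same purview state space, with the Hamming distance between bit-states
#' as the ground metric (each unit of probability pays 1 per bit it must
#' flip). Solved as an exact minimum-cost flow, not an approximation, because
#' mechanism-level integrated information values are typically of order
#' 1e-2 and approximation error would dominate them.
#'
#' @param p,q Numeric probability vectors of equal power-of-two length,
#'   states indexed little-endian.
#' @return Nonnegative scalar distance.
#' @examples
#' emd(c(1, 0, 0, 0), c(0, 0, 0, 1))  # point mass 00 -> 11: Hamming 2
#' @export
emd <- function(p, q) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (length(p) != length(q)) stop("`p` and `q` must share a state space")
  if (abs(sum(p) - sum(q)) > 1e-8) stop("`p` and `q` must carry equal mass")
  cpp_emd_hamming(p, q)
}

new_repertoire <- function(probs, purview, direction, degenerate = FALSE) {
  structure(as.numeric(probs),
            purview = as.integer(purview),
            direction = direction,
            degenerate = degenerate,
            class = "iit_repertoire")
}

#' @export
print.iit_repertoire <- function(x, ...) {
  p <- attr(x, "purview")
  cat(attr(x, "direction"), "repertoire over purview {",
      paste(p, collapse = ","), "}\n")
  v <- as.numeric(x)
  names(v) <- vapply(0:(length(v) - 1), function(s)
    paste(rev(state_from_index(s, length(p))), collapse = ""), character(1))
  print(round(v, 4))
  if (isTRUE(attr(x, "degenerate"))) {
    cat("(degenerate: zero normalizer, uniform returned)\n")
  }
  invisible(x)
}

check_mech_args <- function(tpm, mechanism, mech_state, purview,
                            purview_required = TRUE) {
  n <- ncol(tpm)
  if (length(mechanism) != length(mech_state)) {
    stop("`mech_state` must give one bit per mechanism node")
  }
  if (length(mechanism)) {
    if (any(mechanism < 1 | mechanism > n)) stop("mechanism node outside system")
    if (is.unsorted(mechanism, strictly = TRUE)) {
      stop("`mechanism` must be strictly increasing node positions")
    }
  }
  if (purview_required && length(purview) == 0) stop("`purview` must be non-empty")
  if (length(purview)) {
    if (any(purview < 1 | purview > n)) stop("purview node outside system")
    if (is.unsorted(purview, strictly = TRUE)) {
      stop("`purview` must be strictly increasing node positions")
    }
  }
  if (!all(mech_state %in% c(0, 1))) stop("`mech_state` must be binary")
  invisible(NULL)
}

#' Effect repertoire of a mechanism over a purview
#'
#' Probability distribution over the purview's states at `t + tau` given that
#' the mechanism is clamped to `mech_state` at `t`, with nodes outside the
#' mechanism marginalized under the uniform maximum-entropy distribution.
#' Under the conditional-independence assumption the repertoire factorizes
#' over purview nodes. An empty mechanism yields the unconstrained effect
#' repertoire.
#'
#' @param tpm State-by-node TPM ([as_tpm()] / [estimate_tpm()]).
#' @param mechanism Integer node positions (ascending); may be empty.
#' @param mech_state 0/1 vector, one bit per mechanism node.
#' @param purview Integer node positions (ascending), non-empty.
#' @return An `iit_repertoire` of length `2^|purview|`.
#' @export
effect_repertoire <- function(tpm, mechanism, mech_state, purview) {
  check_mech_args(tpm, mechanism, mech_state, purview)
  r <- cpp_effect_rep(unclass_matrix(tpm), nodes_to_mask(mechanism),
                      state_index_or_zero(mech_state), nodes_to_mask(purview))
  new_repertoire(r, purview, "effect")
}

#' Cause repertoire of a mechanism over a purview
#'
#' Bayesian inversion of the TPM: the probability over purview states at
#' `t - tau`, proportional to the product over mechanism nodes of the
#' likelihood of observing that node's current state, with non-purview past
#' nodes marginalized uniformly. A zero normalizer (the mechanism state is
#' unreachable from every purview state) returns the uniform distribution,
#' flagged via the `degenerate` attribute. An empty mechanism yields the
#' uniform (unconstrained cause) repertoire.
#'
#' @inheritParams effect_repertoire
#' @return An `iit_repertoire` of length `2^|purview|`.
#' @export
cause_repertoire <- function(tpm, mechanism, mech_state, purview) {
  check_mech_args(tpm, mechanism, mech_state, purview)
  r <- cpp_cause_rep(unclass_matrix(tpm), nodes_to_mask(mechanism),
                     state_index_or_zero(mech_state), nodes_to_mask(purview))
  new_repertoire(r$probs, purview, "cause", degenerate = r$degenerate)
}

state_index_or_zero <- function(bits) {
  if (length(bits) == 0L) return(0L)
  state_index(bits)
}

unclass_matrix <- function(tpm) {
  m <- as.matrix(tpm)
  attributes(m) <- attributes(m)["dim"]
  m
}
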