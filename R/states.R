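#' Map a binary state vector to its state index
#'
#' States are indexed little-endian: the node with the lowest channel label is
#' the least significant bit, so `c(1, 0, 0)` maps to index 1 and row 2 of a
#' state-by-node TPM. Indices start at 0; row `s + 1` of a TPM corresponds to
#' state index `s`.
#'
#' @param bits Integer vector of 0/1 values, one per node, first node first.
#' @return A single integer state index in `[0, 2^n - 1]`.
#' @seealso [state_from_index()]
#' @examples
#' state_index(c(0, 0, 0, 0))
#' state_index(c(1, 0, 0, 0))
#' @export
state_index <- function(bits) {
  if (!all(bits %in% c(0, 1))) stop("`bits` must contain only 0 and 1")
  n <- length(bits)
  if (n < 1L) stop("`bits` must have positive length")
  as.integer(sum(bits * 2^(seq_len(n) - 1L)))
}

#' Recover the binary state vector for a state index
#'
#' Inverse of [state_index()] under the little-endian convention.
#'
#' @param index Integer state index in `[0, 2^n - 1]`.
#' @param n_nodes Number of nodes.
#' @return Integer vector of 0/1 values of length `n_nodes`.
#' @examples
#' state_from_index(5, 4)
#' @export
state_from_index <- function(index, n_nodes) {
  if (index < 0 || index >= 2^n_nodes) stop("`index` out of range for ", n_nodes, " nodes")
  as.integer(bitwAnd(bitwShiftR(as.integer(index), seq_len(n_nodes) - 1L), 1L))
}

# --- internal bit-mask helpers (node positions are 1-based within a system) --

nodes_to_mask <- function(nodes) {
  if (length(nodes) == 0L) return(0L)
  if (anyDuplicated(nodes)) stop("node sets must not contain duplicates")
  as.integer(sum(2^(as.integer(nodes) - 1L)))
}

mask_to_nodes <- function(mask, n) {
  which(bitwAnd(as.integer(mask), 2^(seq_len(n) - 1L)) > 0L)
}

# mechanism/purview state restricted to `nodes`, packed little-endian
local_state <- function(system_state, nodes) {
  if (length(nodes) == 0L) return(0L)
  state_index(system_state[nodes])
}

# canonical mechanism labels for an n-node system: masks 1 .. 2^n - 1,
# printed as concatenated member positions ("1", "12", "134", ...)
mechanism_labels <- function(n) {
  vapply(seq_len(2^n - 1L), function(m) {
    paste(mask_to_nodes(m, n), collapse = "")
  }, character(1))
}
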