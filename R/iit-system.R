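#' Enumerate all unidirectional system cuts
#'
#' A unidirectional cut severs all influences from one non-empty part onto
#' its complement, leaving the reverse direction intact, so an n-node system
#' has `2^n - 2` ordered bipartitions. Cuts are enumerated in ascending order
#' of the from-part bit mask; ties in the system-level minimum are broken by
#' this order.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @return A tibble with list-columns `from` and `to` (node positions) and
#'   the integer `from_mask`.
#' @examples
#' enumerate_cuts(2)   # {1}->{2} and {2}->{1}
#' nrow(enumerate_cuts(4))  # 14
#' @export
enumerate_cuts <- function(n_nodes) {
  if (n_nodes < 2) stop("cuts need at least 2 nodes")
  masks <- seq_len(2^n_nodes - 2L)
  tibble::tibble(
    from_mask = masks,
    from = lapply(masks, mask_to_nodes, n = n_nodes),
    to = lapply(masks, function(m) mask_to_nodes(bitwAnd(bitwNot(m), 2^n_nodes - 1L), n_nodes))
  )
}

#' Apply a unidirectional noising cut to a TPM
#'
#' Influences from the from-part into the to-part are replaced by statistical
#' noise: each to-part node's conditional on-probability is re-computed by
#' marginalizing the from-part's current-state bits under the uniform
#' distribution. Connections within the from-part, within the to-part, and
#' from the to-part back into the from-part are untouched. Cutting
#' connections that do not exist leaves the TPM unchanged, and the operation
#' is idempotent.
#'
#' @param tpm State-by-node TPM.
#' @param from Node positions of the from-part (or a single integer bit
#'   mask wrapped in `I()`), non-empty, proper subset of the system.
#' @return An `iit_tpm` of the cut system.
#' @export
apply_cut <- function(tpm, from) {
  n <- ncol(tpm)
  mask <- if (inherits(from, "AsIs")) as.integer(from) else nodes_to_mask(from)
  if (mask < 1 || mask > 2^n - 2) {
    stop("`from` must be a non-empty proper subset of the system")
  }
  out <- cpp_apply_cut(unclass_matrix(tpm), mask)
  as_tpm(out, tau_samples = attr(tpm, "tau_samples") %||% 1L)
}

#' Distance between a full and a cut cause-effect structure
#'
#' Sums, over mechanisms, the phi-weighted earth mover's distances between
#' the full and cut core repertoires (cause plus effect, each expanded to the
#' full n-node space with maximum-entropy filling of off-purview nodes).
#' Phi is the "earth" being moved, so each mechanism's repertoire distance is
#' weighted by the smaller of its two phi values, and any residual
#' `|phi_full - phi_cut|` is transported to the maximally uninformative
#' distributions: the uniform (unconstrained cause) repertoire and the
#' unconstrained effect repertoire of the larger-phi side's system.
#'
#' @param full,cut `iit_ces` objects over the same mechanism census and
#'   system state.
#' @return Nonnegative scalar distance.
#' @export
ces_distance <- function(full, cut) {
  if (!inherits(full, "iit_ces") || !inherits(cut, "iit_ces")) {
    stop("`full` and `cut` must be iit_ces objects")
  }
  if (full$n != cut$n || !identical(full$state, cut$state)) {
    stop("structures must share the mechanism census and system state")
  }
  n <- full$n
  ns <- 2^n
  unif <- rep(1 / ns, ns)
  total <- 0
  for (mask in seq_len(ns - 1)) {
    df <- full$details[[mask]]
    dc <- cut$details[[mask]]
    w <- min(df$phi, dc$phi)
    if (w > 0) {
      dcse <- emd(df$cause$repertoire_full, dc$cause$repertoire_full)
      deff <- sum(abs(df$effect$marginals - dc$effect$marginals))
      total <- total + w * (dcse + deff)
    }
    resid <- abs(df$phi - dc$phi)
    if (resid > 0) {
      big <- if (df$phi >= dc$phi) df else dc
      unc_eff <- if (df$phi >= dc$phi) full$unconstrained_effect else cut$unconstrained_effect
      eff_big <- marginals_to_rep(big$effect$marginals)
      dcse <- emd(big$cause$repertoire_full, unif)
      deff <- emd(eff_big, unc_eff)
      total <- total + resid * (dcse + deff)
    }
  }
  total
}

marginals_to_rep <- function(m) {
  n <- length(m)
  r <- rep(1, 2^n)
  for (x in 0:(2^n - 1)) {
    bits <- state_from_index(x, n)
    r[x + 1] <- prod(ifelse(bits == 1, m, 1 - m))
  }
  r
}

#' System-level integrated information
#'
#' Computes the cause-effect structure of the full system, applies every
#' unidirectional cut, and returns the minimum over cuts of the structure
#' distance ([ces_distance()]) between the full and cut systems. A purely
#' feedforward system scores zero, because cutting the (non-existent)
#' feedback direction changes nothing.
#'
#' @inheritParams compute_ces
#' @return An object of class `iit_system_phi` with elements `big_phi`,
#'   `minimal_cut` (list with `from`, `to`), `full_ces`, `cut_ces` (the
#'   structure under the minimal cut), `cut_distances` (one per cut, `NA`
#'   for cuts skipped once the minimum had provably been reached) and
#'   `state`.
#' @seealso [tidy.iit_system_phi()], [glance.iit_system_phi()]
#' @export
compute_big_phi <- function(tpm, system_state) {
  n <- ncol(tpm)
  if (n < 2) stop("system-level integrated information needs >= 2 nodes")
  if (length(system_state) != n) stop("`system_state` must cover all nodes")
  res <- cpp_big_phi_all(unclass_matrix(tpm))
  s <- state_index(system_state)
  mincut_mask <- res$min_cut[s + 1L]
  full_ces <- compute_ces(tpm, system_state, label = "full")
  cut_ces <- compute_ces(apply_cut(tpm, I(mincut_mask)), system_state,
                         label = "cut")
  structure(list(
    big_phi = res$big_phi[s + 1L],
    minimal_cut = list(from = mask_to_nodes(mincut_mask, n),
                       to = mask_to_nodes(bitwAnd(bitwNot(mincut_mask), 2^n - 1L), n)),
    full_ces = full_ces,
    cut_ces = cut_ces,
    cut_distances = res$cut_distances[, s + 1L],
    state = as.integer(system_state)
  ), class = "iit_system_phi")
}

#' @export
print.iit_system_phi <- function(x, ...) {
  cat("System-level integrated information\n")
  cat("  state:", paste(rev(x$state), collapse = ""),
      " Phi =", signif(x$big_phi, 6), "\n")
  cat("  minimal cut: {", paste(x$minimal_cut$from, collapse = ","), "} -> {",
      paste(x$minimal_cut$to, collapse = ","), "}\n")
  invisible(x)
}

#' Per-state system analysis of a TPM
#'
#' Engine entry point used by the study pipeline: computes, for every system
#' state at once, the system-level integrated information, the minimal cut,
#' and the full-system mechanism phi values (the per-state IIS).
#'
#' @param tpm State-by-node TPM.
#' @return A list with `big_phi` (length `2^n`), `min_cut_mask` (integer),
#'   and `phi_matrix` (`2^n - 1` mechanisms by `2^n` states).
#' @export
system_phi_by_state <- function(tpm) {
  res <- cpp_big_phi_all(unclass_matrix(tpm))
  rownames(res$phi_matrix) <- mechanism_labels(ncol(tpm))
  list(big_phi = res$big_phi, min_cut_mask = res$min_cut,
       phi_matrix = res$phi_matrix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
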