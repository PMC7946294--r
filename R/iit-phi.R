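#' Mechanism-level integrated information over one purview
#'
#' Enumerates every bipartition of (mechanism, purview) into two parts —
#' severed mechanism-to-purview influences are replaced by noise, i.e. the
#' cut variables are marginalized under maximum entropy — and returns the
#' minimum earth mover's distance between the whole repertoire and the
#' product of the parts' repertoires (the minimum-information partition).
#' The trivial partition (one part holding everything) is excluded, as is
#' any part with both components empty. Ties are broken by the first
#' partition in a fixed enumeration order.
#'
#' @inheritParams effect_repertoire
#' @param direction `"cause"` or `"effect"`.
#' @return A list with `phi` (nonnegative scalar) and `partition`, itself a
#'   list of two parts, each with `mechanism` and `purview` node vectors.
#' @export
phi_mip <- function(tpm, mechanism, mech_state, purview,
                    direction = c("effect", "cause")) {
  direction <- match.arg(direction)
  check_mech_args(tpm, mechanism, mech_state, purview)
  if (length(mechanism) == 0L) stop("`mechanism` must be non-empty")
  n <- ncol(tpm)
  res <- cpp_phi_mip(unclass_matrix(tpm), nodes_to_mask(mechanism),
                     state_index_or_zero(mech_state), nodes_to_mask(purview),
                     direction == "cause")
  list(
    phi = res$phi,
    partition = list(
      part1 = list(mechanism = mask_to_nodes(res$part1_mech, n),
                   purview = mask_to_nodes(res$part1_purview, n)),
      part2 = list(mechanism = mask_to_nodes(res$part2_mech, n),
                   purview = mask_to_nodes(res$part2_purview, n))
    )
  )
}

#' Core cause or core effect of a mechanism
#'
#' Scans all non-empty purviews and returns the one over which the mechanism
#' generates the most integrated information (the argmax of [phi_mip()]).
#' Ties go to the larger purview, then to the lexicographically first node
#' set. A mechanism that constrains nothing in the chosen direction returns
#' phi = 0.
#'
#' @inheritParams phi_mip
#' @return A list with `purview` (node vector), `repertoire`
#'   (an `iit_repertoire` over that purview) and `phi`.
#' @export
core_repertoire <- function(tpm, mechanism, mech_state,
                            direction = c("effect", "cause")) {
  direction <- match.arg(direction)
  check_mech_args(tpm, mechanism, mech_state, purview = integer(0),
                  purview_required = FALSE)
  if (length(mechanism) == 0L) stop("`mechanism` must be non-empty")
  n <- ncol(tpm)
  res <- cpp_core(unclass_matrix(tpm), nodes_to_mask(mechanism),
                  state_index_or_zero(mech_state), direction == "cause")
  purview <- mask_to_nodes(res$purview, n)
  list(purview = purview,
       repertoire = new_repertoire(res$repertoire, purview, direction),
       phi = res$phi)
}

#' Concept of a mechanism in a system state
#'
#' Combines the core cause and core effect of a mechanism: the concept's
#' integrated information is `phi = min(phi_cause, phi_effect)`. Concepts
#' with phi = 0 are retained (they simply contribute nothing downstream).
#'
#' @inheritParams phi_mip
#' @param system_state 0/1 vector over all nodes; supplies the mechanism
#'   state.
#' @return An object of class `iit_concept`: a list with `mechanism`,
#'   `core_cause`, `core_effect` (each as in [core_repertoire()]) and `phi`.
#' @export
concept <- function(tpm, mechanism, system_state) {
  n <- ncol(tpm)
  if (length(system_state) != n) stop("`system_state` must cover all nodes")
  mech_state <- system_state[mechanism]
  cc <- core_repertoire(tpm, mechanism, mech_state, "cause")
  ce <- core_repertoire(tpm, mechanism, mech_state, "effect")
  structure(list(mechanism = mechanism, core_cause = cc, core_effect = ce,
                 phi = min(cc$phi, ce$phi)),
            class = "iit_concept")
}

#' @export
print.iit_concept <- function(x, ...) {
  cat("Concept of mechanism {", paste(x$mechanism, collapse = ","), "}: phi =",
      signif(x$phi, 6), "\n")
  cat("  core cause  {", paste(x$core_cause$purview, collapse = ","),
      "} phi_cause =", signif(x$core_cause$phi, 6), "\n")
  cat("  core effect {", paste(x$core_effect$purview, collapse = ","),
      "} phi_effect =", signif(x$core_effect$phi, 6), "\n")
  invisible(x)
}

#' Cause-effect structure of a system in a state
#'
#' Computes one concept per non-empty mechanism (2^n - 1 concepts, in
#' canonical mechanism order: masks ascending, i.e. {1}, {2}, {1,2}, {3}, ...)
#' and collects the full detail needed to compare structures, including each
#' core repertoire expanded to the full n-node state space with
#' maximum-entropy filling of off-purview nodes.
#'
#' @inheritParams concept
#' @param label `"full"` or `"cut"`, recorded on the object.
#' @return An object of class `iit_ces`; see [tidy.iit_ces()] for the
#'   mechanism-level summary table.
#' @export
compute_ces <- function(tpm, system_state, label = "full") {
  n <- ncol(tpm)
  if (length(system_state) != n) stop("`system_state` must cover all nodes")
  if (!all(system_state %in% c(0, 1))) stop("`system_state` must be binary")
  m <- unclass_matrix(tpm)
  tab <- cpp_concept_table(m)
  s <- state_index(system_state)
  details <- vector("list", 2^n - 1)
  for (mask in seq_len(2^n - 1)) {
    nodes <- mask_to_nodes(mask, n)
    msl <- local_state(as.integer(system_state), nodes)
    details[[mask]] <- tab[[mask]][[msl + 1L]]
  }
  phis <- vapply(details, function(d) d$phi, numeric(1))
  concepts <- tibble::tibble(
    mechanism = mechanism_labels(n),
    size = vapply(seq_len(2^n - 1), function(m) length(mask_to_nodes(m, n)), integer(1)),
    phi_cause = vapply(details, function(d) d$cause$phi, numeric(1)),
    phi_effect = vapply(details, function(d) d$effect$phi, numeric(1)),
    phi = phis,
    core_cause = lapply(details, function(d) mask_to_nodes(d$cause$purview, n)),
    core_effect = lapply(details, function(d) mask_to_nodes(d$effect$purview, n))
  )
  structure(list(concepts = concepts, details = details,
                 state = as.integer(system_state), n = n, label = label,
                 unconstrained_effect = cpp_effect_rep(m, 0L, 0L, 2^n - 1L),
                 tpm = tpm),
            class = "iit_ces")
}

#' @export
print.iit_ces <- function(x, ...) {
  cat("Cause-effect structure (", x$label, ") of ", x$n, "-node system in state ",
      paste(rev(x$state), collapse = ""), "\n", sep = "")
  print(x$concepts[, c("mechanism", "phi_cause", "phi_effect", "phi")])
  invisible(x)
}

#' Integrated information structure (IIS) of a cause-effect structure
#'
#' The IIS keeps only the mechanism-level phi values of the structure, in
#' canonical mechanism order (2^n - 1 values; 15 for a 4-channel set).
#'
#' @param ces An `iit_ces`.
#' @return Named numeric vector of mechanism phi values.
#' @export
iis_vector <- function(ces) {
  stats::setNames(ces$concepts$phi, ces$concepts$mechanism)
}
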