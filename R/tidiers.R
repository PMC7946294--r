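#' Tidy a cause-effect structure
#'
#' One row per mechanism with its core purviews and phi values.
#'
#' @param x An `iit_ces`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.iit_ces <- function(x, ...) x$concepts

#' Glance at a cause-effect structure
#'
#' @param x An `iit_ces`.
#' @param ... Unused.
#' @return One-row tibble: node count, system state, concept count, number
#'   of concepts with positive phi, summed phi.
#' @export
glance.iit_ces <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n,
    state = paste(rev(x$state), collapse = ""),
    n_concepts = nrow(x$concepts),
    n_positive = sum(x$concepts$phi > 0),
    sum_phi = sum(x$concepts$phi)
  )
}

#' Tidy a system-level result
#'
#' Mechanism-level comparison of the full and minimally cut structures.
#'
#' @param x An `iit_system_phi`.
#' @param ... Unused.
#' @return Tibble with per-mechanism phi under the full and cut system.
#' @export
tidy.iit_system_phi <- function(x, ...) {
  full <- x$full_ces$concepts
  cut <- x$cut_ces$concepts
  tibble::tibble(mechanism = full$mechanism, size = full$size,
                 phi_full = full$phi, phi_cut = cut$phi)
}

#' Glance at a system-level result
#'
#' @param x An `iit_system_phi`.
#' @param ... Unused.
#' @return One-row tibble: Phi, the minimal cut, and the state.
#' @export
glance.iit_system_phi <- function(x, ...) {
  tibble::tibble(
    big_phi = x$big_phi,
    minimal_cut = paste0("{", paste(x$minimal_cut$from, collapse = ","),
                         "}->{", paste(x$minimal_cut$to, collapse = ","), "}"),
    state = paste(rev(x$state), collapse = "")
  )
}

#' Plot the integrated information structure of a CES
#'
#' Bar chart of mechanism phi values (the IIS), grouped by mechanism size.
#'
#' @param object An `iit_ces`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iit_ces <- function(object, ...) {
  d <- object$concepts
  d$mechanism <- factor(d$mechanism, levels = d$mechanism)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mechanism, y = .data$phi,
                                  fill = factor(.data$size))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mechanism", y = expression(varphi),
                  fill = "size",
                  title = "Integrated information structure") +
    ggplot2::theme_minimal()
}

#' Plot full versus cut mechanism phi values
#'
#' @param object An `iit_system_phi`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iit_system_phi <- function(object, ...) {
  d <- tidy.iit_system_phi(object)
  d <- tidyr::pivot_longer(d, c("phi_full", "phi_cut"),
                           names_to = "system", values_to = "phi")
  d$mechanism <- factor(d$mechanism, levels = unique(d$mechanism))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mechanism, y = .data$phi,
                                  fill = .data$system)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "mechanism", y = expression(varphi),
                  title = sprintf("Phi = %.4g under minimal cut", object$big_phi)) +
    ggplot2::theme_minimal()
}

#' Plot condition-wise Phi of a study result
#'
#' Boxplot of epoch-averaged system-level integrated information per
#' condition, across subjects and channel sets.
#'
#' @param results An `iis_study_result` from [run_study()].
#' @return A ggplot object.
#' @export
plot_phi_by_condition <- function(results) {
  d <- summarize_phi(results)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$big_phi,
                                  fill = .data$condition)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = expression(Phi),
                  title = "System-level integrated information by condition") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
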