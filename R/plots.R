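#' Plot bifurcation loci in the (P, Q) plane
#'
#' @param object a \code{bifurcation_loci} tibble from [bifurcation_scan()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.bifurcation_loci <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$P, y = .data$Q,
                                       colour = .data$kind)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = "Bifurcation skeleton of the isolated node",
                  colour = "locus") +
    ggplot2::theme_minimal()
}

#' Heat map of a functional-connectivity matrix
#'
#' @param object an \code{fc_matrix}.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fc_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(object$n), j = seq_len(object$n))
  df$value <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste("Functional connectivity:", object$measure),
                  x = "node j", y = "node i") +
    ggplot2::theme_minimal()
}

#' Phase interaction function H(theta)
#'
#' @param object a \code{phase_interaction}.
#' @param ... unused.
#' @return A ggplot of H over one period with the zero line.
#' @export
autoplot.phase_interaction <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$theta, y = .data$H)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "darkgreen") +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(
      title = sprintf("H(theta) at (P, Q) = (%g, %g); H'(0) = %.4g",
                      object$params$P, object$params$Q, object$H_prime_0),
      x = "phase difference theta (cycles)", y = "H") +
    ggplot2::theme_minimal()
}

#' Parameter-plane map of H'(0)
#'
#' @param object an \code{hprime_map} tibble.
#' @param ... unused.
#' @return A ggplot heat map; non-oscillatory points are blank.
#' @export
autoplot.hprime_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$P, y = .data$Q,
                                       fill = .data$hprime0)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, na.value = "grey90") +
    ggplot2::labs(title = "Stability of the synchronous state",
                  fill = "H'(0)") +
    ggplot2::theme_minimal()
}

#' Parameter-plane maps from a sweep
#'
#' @param object a \code{sweep_result}.
#' @param value column to map (default "jaccard").
#' @param ... unused.
#' @return A ggplot heat map, faceted by FC measure.
#' @export
autoplot.sweep_result <- function(object, value = "jaccard", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$P, y = .data$Q,
                                       fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(title = sprintf("%s over the (P, Q) plane [SC: %s]",
                                  value, attr(object, "sc_label") %||% ""),
                  fill = value) +
    ggplot2::theme_minimal()
}

#' Stacked traces of simulated node activity
#'
#' @param object a \code{wc_sim}.
#' @param t_max plot at most this many time units from the start of the
#'   record (default 200).
#' @param ... unused.
#' @return A ggplot of vertically offset u-traces, one per node.
#' @export
autoplot.wc_sim <- function(object, t_max = 200, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$time <= object$t0 + t_max)
  df$trace <- df$u + df$node
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$trace,
                                   group = .data$node)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(title = sprintf("u-traces at (P, Q) = (%g, %g)",
                                  object$params$P, object$params$Q),
                  x = "time", y = "node (offset u)") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
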