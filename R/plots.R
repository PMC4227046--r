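# ggplot2 displays for the main result types.

#' @export
autoplot.mn_sweep <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(df, c("voltage", "current"),
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = c("voltage", "current"),
                         labels = c("membrane potential (mV)",
                                    "injected current (nA)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste0(object$protocol_id, " sweep ",
                                 object$sweep_index)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mn_ficurve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$current, y = .data$freq_inst,
                               colour = .data$phase)) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(ascending = "black",
                                            descending = "red")) +
    ggplot2::labs(x = "injected current (nA)",
                  y = "instantaneous frequency (Hz)",
                  title = "F-I curve (triangular ramp)") +
    ggplot2::theme_minimal()
}

#' Plot a rheobase-conductance zero-intercept comparison
#'
#' Scatter of rheobase against input conductance for two groups with their
#' zero-intercept regression lines (the I = G.U law).
#'
#' @param comparison an `mn_slope_comparison` from [compare_slopes()].
#' @param labels length-2 character vector naming the groups.
#' @return a ggplot.
#' @export
plot_slope_comparison <- function(comparison, labels = c("A", "B")) {
  stopifnot(inherits(comparison, "mn_slope_comparison"))
  df <- dplyr::bind_rows(
    tibble::tibble(g = comparison$fit_a$g, i = comparison$fit_a$i,
                   group = labels[1]),
    tibble::tibble(g = comparison$fit_b$g, i = comparison$fit_b$i,
                   group = labels[2]))
  slopes <- tibble::tibble(
    group = labels,
    slope = c(comparison$fit_a$slope, comparison$fit_b$slope))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$i,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(data = slopes,
                         ggplot2::aes(intercept = 0, slope = .data$slope,
                                      colour = .data$group),
                         linetype = "dashed") +
    ggplot2::labs(x = "input conductance (nS)", y = "rheobase (nA)",
                  subtitle = sprintf("U = %.1f vs %.1f mV (t p = %.3g, Chow p = %.3g)",
                                     comparison$fit_a$slope_mv,
                                     comparison$fit_b$slope_mv,
                                     comparison$t_p, comparison$chow_p)) +
    ggplot2::theme_minimal()
}

#' Plot a dendritic morphology (slice-plane projection)
#'
#' @param m an `mn_morphology`.
#' @param z_limit draw nodes deeper than this limit in red.
#' @return a ggplot.
#' @export
plot_morphology <- function(m, z_limit = 50) {
  stopifnot(inherits(m, "mn_morphology"))
  idx <- match(m$parent, m$id)
  seg <- tibble::tibble(x = m$x, y = m$y, xend = m$x[idx], yend = m$y[idx],
                        deep = m$z > z_limit)[!is.na(idx), ]
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$deep),
                          linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey20",
                                            `TRUE` = "red")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
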