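# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a kymograph
#'
#' Space-time raster of an azimuthally averaged field, radial position
#' against time, as used to display the core-shell dynamics.
#'
#' @param object a [kymograph()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.droplet_kymograph <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$r,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "field")) +
    ggplot2::labs(x = "time", y = "radial position") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.droplet_trajectory <- function(object, field = "c_cell", ...) {
  autoplot(kymograph(object, field))
}

#' Plot a core-radius trace
#'
#' @param object a [core_trace()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.core_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$r_core)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "R_tilde"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time", y = "anoxic-core radius") +
    ggplot2::theme_minimal()
}

#' Plot a morphological state diagram
#'
#' Regime labels in the `(kt_inv, R_tilde)` plane on log axes, optionally
#' overlaid with the onset line `R_tilde = 1` and fitted permanence
#' boundaries.
#'
#' @param sweep a [sweep_state_diagram()] result.
#' @param onset draw the horizontal onset line `R_tilde = 1`.
#' @param fit_linear optional [fit_boundary_linear()] object to overlay.
#' @param fit_saturating optional [fit_boundary_saturating()] object.
#' @return a ggplot object.
#' @export
plot_state_diagram <- function(sweep, onset = TRUE, fit_linear = NULL,
                               fit_saturating = NULL) {
  p <- ggplot2::ggplot(sweep,
                       ggplot2::aes(x = .data$kt_inv, y = .data$R_tilde,
                                    colour = .data$label)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tilde(k)[t]^-1), y = expression(tilde(R))) +
    ggplot2::theme_minimal()
  if (onset)
    p <- p + ggplot2::geom_hline(yintercept = 1, linetype = "solid",
                                 colour = "darkorange")
  grid_x <- exp(seq(log(min(sweep$kt_inv)), log(max(sweep$kt_inv)),
                    length.out = 100))
  if (!is.null(fit_linear))
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(kt_inv = grid_x,
                            R_tilde = fit_linear$a / grid_x,
                            label = NA_character_),
      linetype = "dashed", colour = "darkblue")
  if (!is.null(fit_saturating))
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(
        kt_inv = grid_x,
        R_tilde = fit_saturating$A /
          (fit_saturating$B + fit_saturating$C * grid_x),
        label = NA_character_),
      colour = "darkblue")
  p
}
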