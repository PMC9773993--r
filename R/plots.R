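#' Plot a slice profile along the cord
#'
#' Line plot of the slice-mean field magnitude and signed components against
#' z, faceted by tissue — the standard way to read where along the cord the
#' stimulation concentrates and in which direction.
#'
#' @param object A `slice_profile`.
#' @param components Which quantities to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot slice_profile
#' @export
autoplot.slice_profile <- function(object,
                                   components = c("e_norm", "e_long",
                                                  "e_vd", "e_rl"),
                                   ...) {
  long <- object |>
    dplyr::filter(.data$n_voxels > 0) |>
    tidyr::pivot_longer(dplyr::all_of(components),
                        names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z_mid, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$tissue), ncol = 1) +
    ggplot2::labs(x = "z along cord (mm, rostral →)",
                  y = "slice-mean E (V/m)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-segment field maxima
#'
#' @param object A `segment_summary`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot segment_summary
#' @export
autoplot.segment_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("e_norm_max", "e_long_max", "e_vd_max", "e_rl_max"),
    names_to = "quantity", values_to = "value")
  long$segment <- factor(long$segment, levels = unique(object$segment))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$segment, y = .data$value,
                                     fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$tissue), ncol = 1) +
    ggplot2::labs(x = "spinal segment", y = "max slice-mean E (V/m)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
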