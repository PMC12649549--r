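# ggplot2 views of the main result types.

#' Helical-wheel plot
#'
#' Draws each peptide's residues on the helical wheel, coloured by residue
#' class (cationic, hydrophobic, other), faceted by peptide. The radial
#' layout makes the amphipathic segregation of a rotation visible at a
#' glance.
#'
#' @param object A `wheel_projection` tibble from [helical_wheel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(helical_wheel(w5k_library()[1, ]))
#' @method autoplot wheel_projection
#' @export
autoplot.wheel_projection <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(
      class = dplyr::case_when(
        .data$residue %in% c("K", "R", "H") ~ "cationic",
        .data$residue %in% c("W", "F", "L", "I", "V", "M", "A", "Y", "C") ~
          "hydrophobic",
        TRUE ~ "other"
      ),
      x = .data$cos_angle,
      y = .data$sin_angle
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue), size = 3) +
    ggplot2::facet_wrap(~name) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}

#' Dose-response curve plot
#'
#' Response versus log-scaled concentration, optionally with the HC10
#' threshold and estimate marked.
#'
#' @param curve A data frame with `concentration` and `response` columns
#'   (a `peptide` column, if present, maps to colour).
#' @param fit Optional `hc10_fit` from [estimate_hc10()].
#' @return A ggplot object.
#' @export
plot_dose_response <- function(curve, fit = NULL) {
  aes_base <- if ("peptide" %in% names(curve)) {
    ggplot2::aes(x = .data$concentration, y = .data$response,
                 colour = .data$peptide)
  } else {
    ggplot2::aes(x = .data$concentration, y = .data$response)
  }
  p <- ggplot2::ggplot(curve, aes_base) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (µg/mL)", y = "response (%)")
  if (!is.null(fit)) {
    p <- p +
      ggplot2::geom_hline(yintercept = fit$threshold, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = fit$hc10, linetype = "dotted")
  }
  p
}

#' MIC panel heatmap
#'
#' Tile view of a MIC panel on a log2 colour scale, censored cells marked
#' with ">".
#'
#' @param panel A long MIC panel tibble.
#' @return A ggplot object.
#' @examples
#' plot_mic_heatmap(w5k_mic_panel())
#' @export
plot_mic_heatmap <- function(panel) {
  ggplot2::ggplot(panel, ggplot2::aes(x = .data$peptide, y = .data$strain,
                                      fill = log2(.data$mic))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$censored,
                                  paste0(">", format_num(.data$mic)),
                                  format_num(.data$mic))),
      size = 2.5
    ) +
    ggplot2::scale_fill_viridis_c(name = "log2 MIC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
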