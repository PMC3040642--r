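#' Barcode-gap histograms for an audit
#'
#' Plots the two distributions whose separation is the barcode gap: the
#' per-species nearest-neighbour distances and the per-species maximum
#' intraspecific distances (MPD, singletons excluded), both in 0.5%
#' classes.
#'
#' @param object A `barcode_audit` object.
#' @param ... Unused.
#' @return A ggplot object (two facets sharing the distance axis).
#' @export
autoplot.barcode_audit <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$nn_hist,
                  panel = "Nearest-neighbour distance (between species)"),
    dplyr::mutate(object$mpd_hist,
                  panel = "Maximum intraspecific distance (MPD)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lower_pct + 0.25,
                                   y = .data$count)) +
    ggplot2::geom_col(width = 0.45, fill = "grey25") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "K2P distance (%, 0.5% classes)",
                  y = "Number of species") +
    ggplot2::theme_minimal()
}

#' Scatter view of the barcode gap
#'
#' Maximum intraspecific distance against nearest-neighbour distance,
#' one point per (non-singleton) species; points above the identity line
#' lack a local barcode gap. Flagged species are coloured.
#'
#' @param audit A `barcode_audit` object.
#' @return A ggplot object.
#' @export
plot_barcode_gap <- function(audit) {
  df <- dplyr::filter(tidy(audit), !is.na(.data$mpd),
                      !is.na(.data$nn_distance)) |>
    dplyr::mutate(flag = dplyr::case_when(
      .data$sharing ~ "sharing",
      .data$deep_split ~ "deep split",
      .data$low_divergence ~ "low divergence",
      TRUE ~ "none"
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nn_distance * 100,
                                   y = .data$mpd * 100,
                                   colour = .data$flag)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "none" = "grey40", "sharing" = "#d95f02",
      "deep split" = "#7570b3", "low divergence" = "#1b9e77")) +
    ggplot2::labs(x = "Nearest-neighbour distance (%)",
                  y = "Maximum intraspecific distance (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
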