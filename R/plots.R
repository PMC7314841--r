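#' Plot an absorption spectrum
#'
#' @param object An `absorption_spectrum` tibble (e.g. from
#'   [broaden_spectrum()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot absorption_spectrum
#' @export
autoplot.absorption_spectrum <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$frequency_thz, y = .data$alpha)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (THz)",
                  y = expression(alpha ~ (cm^-1))) +
    ggplot2::theme_minimal()
}

#' Plot extracted optical constants
#'
#' Refractive index and absorption coefficient over the valid band, as two
#' stacked panels.
#'
#' @param object An `optical_constants` tibble from
#'   [extract_optical_constants()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot optical_constants
#' @export
autoplot.optical_constants <- function(object, ...) {
  df <- dplyr::filter(object, .data$valid)
  long <- tidyr::pivot_longer(df, c("n", "alpha_cm"),
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, c("n", "alpha_cm"),
                          c("refractive index n",
                            "absorption (cm^-1)"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$frequency_thz, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Frequency (THz)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked-bar chart of species-averaged mode character
#'
#' One bar per (mode, species), stacked by the seven components — the
#' standard way to compare how much of each low-frequency mode is
#' intermolecular translation, libration or intramolecular distortion,
#' and how host and water molecules differ.
#'
#' @param summary A [summarize_unit_cell()] table (a [mode_character()]
#'   table also works; bars are then per molecule).
#' @return A ggplot.
#' @export
plot_mode_character <- function(summary) {
  pcols <- grep("^p_", names(summary), value = TRUE)
  long <- tidyr::pivot_longer(summary, dplyr::all_of(pcols),
                              names_to = "component", values_to = "percent")
  long$component <- factor(long$component, levels = pcols)
  long$mode_label <- sprintf("%.2f THz", long$frequency_thz)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$mode_label, y = .data$percent,
                               fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "Mode", y = "Contribution (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a time-domain trace
#'
#' @param object A [time_domain_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot time_domain_trace
#' @export
autoplot.time_domain_trace <- function(object, ...) {
  df <- tibble::tibble(time_ps = object$time_ps,
                       amplitude = object$amplitude)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ps, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ps)", y = "Field amplitude (a.u.)",
                  subtitle = object$role) +
    ggplot2::theme_minimal()
}
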