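#' Plot a Ks-window hazard-ratio table
#'
#' Hazard ratios with 95% confidence intervals across nested Ks windows;
#' the dashed line at 1 marks equal death rates.
#'
#' @param hazard_table Output of [ks_window_hazard_table()].
#' @return A ggplot object.
#' @export
plot_hazard_table <- function(hazard_table) {
  ht <- dplyr::mutate(hazard_table,
    window = factor(
      sprintf("0 < Ks < %g", .data$window_hi),
      levels = sprintf("0 < Ks < %g", sort(unique(.data$window_hi)))
    )
  )
  ggplot2::ggplot(ht, ggplot2::aes(x = .data$window, y = .data$hazard_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)
    ) +
    ggplot2::labs(
      x = NULL, y = "Hazard ratio (nonrelocalized vs relocalized)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot N-terminal mutation category frequencies
#'
#' Category share of all pairs alongside the PSR frequency within each
#' category.
#'
#' @param ntp_summary Output of [category_frequencies()].
#' @return A ggplot object.
#' @export
plot_ntp_categories <- function(ntp_summary) {
  long <- ntp_summary |>
    dplyr::select("ntp_class", "fraction", "psr_within") |>
    tidyr::pivot_longer(c("fraction", "psr_within"),
      names_to = "measure", values_to = "value"
    ) |>
    dplyr::mutate(
      measure = dplyr::recode(.data$measure,
        fraction = "share of all pairs",
        psr_within = "PSR frequency within category"
      ),
      ntp_class = factor(.data$ntp_class,
        levels = c("NONE", "PARTIAL", "TERMINAL", "COMPLETE")
      )
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$ntp_class, y = .data$value)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "NTP mutation category", y = "Frequency") +
    ggplot2::theme_minimal()
}

#' Cox-Snell residual diagnostic plot for a Cox fit
#'
#' Plots the empirical cumulative hazard of the Cox-Snell residuals
#' against the unit-exponential reference line; points on the diagonal
#' indicate an adequate proportional-hazards fit.
#'
#' @param object A `psr_cox` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.psr_cox <- function(object, ...) {
  cs <- cox_snell_residuals(object)
  r <- sort(cs$residuals$residual)
  df <- tibble::tibble(
    residual = r,
    cumhaz = -log(1 - (seq_along(r) - 0.5) / length(r))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residual, y = .data$cumhaz)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(
      x = "Cox-Snell residual",
      y = "Empirical cumulative hazard",
      subtitle = sprintf("KS distance from Exp(1): %.3f", cs$ks_distance)
    ) +
    ggplot2::theme_minimal()
}
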