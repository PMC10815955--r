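# ggplot2 methods for the result containers.

#' Plot a PLF time-frequency map
#'
#' Heatmap of phase-locking values over the epoch window, one facet per
#' channel; invalid edge cells are blank.
#'
#' @param object A `plf_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plf_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz, fill = .data$plf)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "time from stimulus onset (s)", y = "frequency (Hz)",
                  fill = "PLF")
}

#' Plot epoch-averaged power spectra
#'
#' Mean power per frequency bin over retained epochs, per channel, on a log
#' power scale.
#'
#' @param object A `spectrum_set`.
#' @param fmax Upper frequency limit of the plot, Hz.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum_set <- function(object, fmax = 100, ...) {
  df <- as_tibble(object)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$channel, .data$freq_hz),
    power = mean(.data$power), .groups = "drop"
  )
  df <- dplyr::filter(df, .data$freq_hz > 0, .data$freq_hz <= fmax)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$power,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(power ~ (mu * V^2)))
}

#' Plot Dunnett comparisons
#'
#' Mean differences against the reference arm with 95% single-step
#' simultaneous confidence intervals.
#'
#' @param object A `dunnett_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dunnett_fit <- function(object, ...) {
  ci <- stats::confint(object$glht)$confint
  df <- tibble(
    arm = object$comparisons$arm,
    estimate = ci[, "Estimate"], lwr = ci[, "lwr"], upr = ci[, "upr"]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$arm, .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr)) +
    ggplot2::labs(x = NULL,
                  y = sprintf("mean difference vs %s", object$reference))
}

#' Plot a study report as percent-of-reference bars
#'
#' Arm means with SEM error bars on the percent-of-reference scale,
#' faceted by endpoint and channel.
#'
#' @param report A [build_report()] table (or `assr_study$report`).
#' @return A ggplot.
#' @export
plot_report <- function(report) {
  df <- dplyr::mutate(report,
    facet = ifelse(is.na(.data$channel), .data$endpoint,
                   paste(.data$endpoint, .data$channel, sep = " / "))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$arm, .data$pct_mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$pct_mean - .data$pct_sem,
                   ymax = .data$pct_mean + .data$pct_sem), width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::facet_wrap(~facet, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "% of reference-arm mean")
}
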