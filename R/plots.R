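#' Plot a lifetime spectrum
#'
#' Counts versus time on a log10 count scale — the conventional PALS
#' presentation in which each exponential component appears as a straight
#' tail segment with slope `-1/tau`. An optional fit overlays the model
#' curve and the individual components.
#'
#' @param object A `pals_spectrum`.
#' @param fit Optional `pals_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pals_spectrum
#' @export
autoplot.pals_spectrum <- function(object, fit = NULL, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$counts > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns, y = .data$counts)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time [ns]", y = "counts",
                  title = "Positron lifetime spectrum") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = fit_curves(fit)$total, colour = "red", linewidth = 0.4
    ) + ggplot2::geom_line(
      data = fit_curves(fit)$components,
      ggplot2::aes(group = .data$component, colour = factor(.data$component)),
      linetype = "dashed", linewidth = 0.4
    ) + ggplot2::labs(colour = "component")
  }
  p
}

# Reconstruct model curves (total and per component) from a fit.
fit_curves <- function(fit) {
  s <- fit$settings
  s$t0_channel <- fit$t0_channel
  s$irf_fwhm <- fit$irf_fwhm
  w_ns <- s$channel_width / 1000
  time_ns <- (seq_len(s$n_channels) - 1L - fit$t0_channel) * w_ns
  comp <- purrr::map_dfr(seq_len(fit$n_components), function(i) {
    a <- fit$signal_counts * fit$intensities[i] / 100
    tibble::tibble(
      component = i,
      time_ns = time_ns,
      counts = a * component_channel_probs(fit$lifetimes[i], s) + fit$background
    )
  })
  total <- comp |>
    dplyr::group_by(.data$time_ns) |>
    dplyr::summarise(counts = sum(.data$counts) -
                       (dplyr::n() - 1) * fit$background,
                     .groups = "drop")
  list(total = total, components = comp)
}

#' Plot a fitted decomposition
#'
#' @param object A `pals_fit`.
#' @param spectrum Optional `pals_spectrum` to show behind the model.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pals_fit
#' @export
autoplot.pals_fit <- function(object, spectrum = NULL, ...) {
  if (!is.null(spectrum)) return(autoplot(spectrum, fit = object))
  cv <- fit_curves(object)
  ggplot2::ggplot(cv$components,
                  ggplot2::aes(x = .data$time_ns, y = .data$counts,
                               colour = factor(.data$component))) +
    ggplot2::geom_line(linetype = "dashed", linewidth = 0.4) +
    ggplot2::geom_line(data = cv$total, colour = "black", linewidth = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time [ns]", y = "counts", colour = "component",
                  title = "Fitted decay components") +
    ggplot2::theme_minimal()
}

#' Plot replicate free-volume parameters per sample
#'
#' @param data A data frame with `sample` and numeric parameter columns,
#'   e.g. the `free_volume` tibble from [run_pipeline()] or
#'   [skin_reference()].
#' @param parameters Columns to facet over.
#' @return A ggplot object.
#' @export
plot_replicates <- function(data, parameters = c("tau3", "I3", "R", "Vf", "fv")) {
  parameters <- intersect(parameters, names(data))
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(data),
                  dplyr::all_of(c("sample", parameters))),
    -"sample", names_to = "parameter", values_to = "value"
  )
  long$parameter <- factor(long$parameter, levels = parameters)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          colour = "red", linewidth = 0.25) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL,
                  title = "Replicate free-volume parameters") +
    ggplot2::theme_minimal()
}
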