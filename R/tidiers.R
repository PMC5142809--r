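# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a periodogram
#'
#' @param x A `periodogram`.
#' @param ... Unused.
#' @return Tibble: `frequency_mhz`, `power`, `method`.
#' @export
tidy.periodogram <- function(x, ...) {
  tibble::tibble(frequency_mhz = x$frequency_mhz, power = x$power,
                 method = attr(x, "method"))
}

#' Glance at a periodogram
#'
#' @param x A `periodogram`.
#' @param band Band for [dominant_peak()], mHz.
#' @param ... Unused.
#' @return One-row tibble: dominant `frequency_mhz` and `power`, `method`,
#'   `n`, `low_resolution`.
#' @export
glance.periodogram <- function(x, band = c(0, 250), ...) {
  pk <- dominant_peak(x, band)
  tibble::tibble(frequency_mhz = pk$frequency_mhz, power = pk$power,
                 method = attr(x, "method"), n = attr(x, "n"),
                 low_resolution = isTRUE(attr(x, "low_resolution")))
}

#' Tidy an egg-aligned ensemble
#'
#' @param x An `aligned_ensemble`.
#' @param ... Unused.
#' @return Long tibble: `event`, `time_rel_s`, `value`, plus `event = "median"`
#'   rows for the pointwise median trace.
#' @export
tidy.aligned_ensemble <- function(x, ...) {
  events <- if (x$n_events) {
    purrr::map_dfr(seq_len(x$n_events), function(i) {
      tibble::tibble(event = as.character(i), time_rel_s = x$time_rel_s,
                     value = x$snippets[i, ])
    })
  } else {
    tibble::tibble(event = character(), time_rel_s = numeric(),
                   value = numeric())
  }
  dplyr::bind_rows(events,
                   tibble::tibble(event = "median", time_rel_s = x$time_rel_s,
                                  value = x$median))
}

#' Glance at an egg-aligned ensemble
#'
#' @param x An `aligned_ensemble`.
#' @param ... Unused.
#' @return One-row tibble: `n_events`, `n_excluded`,
#'   `median_peak_offset_s`, `median_peak_time_rel_s` (argmax of the median
#'   trace).
#' @export
glance.aligned_ensemble <- function(x, ...) {
  tibble::tibble(
    n_events = x$n_events, n_excluded = x$n_excluded,
    median_peak_offset_s = if (x$n_events) median(x$offsets$peak_offset_s)
                           else NA_real_,
    median_peak_time_rel_s = if (x$n_events)
      x$time_rel_s[which.max(x$median)] else NA_real_)
}

#' Tidy a phase-uniformity test
#'
#' @param x A `phase_uniformity` result.
#' @param ... Unused.
#' @return Tibble with one row per reported test.
#' @export
tidy.phase_uniformity <- function(x, ...) {
  tibble::tibble(
    test = c("binned_rank_vs_uniform", "rayleigh"),
    statistic = c(x$statistic, x$rayleigh_statistic),
    p_value = c(x$p_value, x$rayleigh_p),
    addition = c(FALSE, TRUE))
}

#' Glance at a full analysis
#'
#' @param x An `egg_analysis`.
#' @param ... Unused.
#' @return Tibble with one row per cell type: transient counts, mean and
#'   median state-resolved intervals, egg-coupling fractions, median
#'   dominant frequency, median egg-aligned peak offset.
#' @export
glance.egg_analysis <- function(x, ...) {
  purrr::map_dfr(names(x$cells), function(ct) {
    s <- x$summary$cells[[ct]]
    tibble::tibble(
      cell_type = ct,
      n_transients = s$n_transients,
      mean_active_interval_s = s$intervals$active$mean %||% NA_real_,
      median_active_interval_s = s$intervals$active$median %||% NA_real_,
      mean_inactive_interval_s = s$intervals$inactive$mean %||% NA_real_,
      frac_transients_egg_coupled = s$egg_coupling$frac_transients_coupled,
      frac_eggs_covered = s$egg_coupling$frac_eggs_covered,
      dominant_frequency_mhz = s$dominant_frequency_mhz,
      median_peak_offset_s = s$median_peak_offset_s)
  })
}

#' Plot a delta-R/R trace with detected transients
#'
#' @param object A [ratio_trace()] with a `droverr` column.
#' @param transients Optional [detect_transients()] table to mark peaks.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ratio_trace <- function(object, transients = NULL, ...) {
  y <- if ("droverr" %in% names(object)) "droverr" else "ratio"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data[[y]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = if (y == "droverr") expression(Delta * R / R)
                      else "GCaMP/mCherry ratio") +
    ggplot2::theme_minimal()
  if (!is.null(transients) && nrow(transients)) {
    p <- p + ggplot2::geom_point(
      data = transients,
      ggplot2::aes(x = .data$peak_time_s, y = .data$amplitude),
      color = "red", size = 1)
  }
  p
}

#' Plot a periodogram with its dominant peak
#'
#' @param object A `periodogram`.
#' @param band Band highlighted and searched for the dominant peak, mHz.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.periodogram <- function(object, band = c(0, 250), ...) {
  pk <- dominant_peak(object, band)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frequency_mhz, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk, color = "red") +
    ggplot2::coord_cartesian(xlim = band) +
    ggplot2::labs(x = "frequency (mHz)", y = "power") +
    ggplot2::theme_minimal()
}

#' Plot an egg-aligned ensemble
#'
#' @param object An `aligned_ensemble`.
#' @param ... Unused.
#' @return A ggplot: per-event snippets (grey) and the pointwise median.
#' @export
autoplot.aligned_ensemble <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(dplyr::filter(df, .data$event != "median"),
                  ggplot2::aes(x = .data$time_rel_s, y = .data$value,
                               group = .data$event)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.2) +
    ggplot2::geom_line(data = dplyr::filter(df, .data$event == "median"),
                       color = "red", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time relative to egg release (s)",
                  y = paste0(object$value, " (normalized)")) +
    ggplot2::theme_minimal()
}

#' Plot a circular phase histogram
#'
#' @param histogram Output of [bin_phases()].
#' @param reference Draw the uniform reference level (12.5% for 8 bins).
#' @return A ggplot bar chart over the phase bins.
#' @export
plot_phase_histogram <- function(histogram, reference = TRUE) {
  p <- ggplot2::ggplot(histogram,
                       ggplot2::aes(x = .data$bin_start +
                                      (.data$bin_end - .data$bin_start) / 2,
                                    y = .data$percent)) +
    ggplot2::geom_col(width = 40, fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = "body-bend phase (degrees)", y = "% of transients") +
    ggplot2::theme_minimal()
  if (reference) {
    p <- p + ggplot2::geom_hline(yintercept = 100 / nrow(histogram),
                                 linetype = 2)
  }
  p
}
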