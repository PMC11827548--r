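# ggplot2 displays for the package's result types.

#' Plot a hypnogram
#'
#' Classic stage-trace display with wake at the top and REM at the bottom.
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  es <- epoch_s(object)
  df <- tibble(
    time_min = (object$epoch * es) / 60,
    stage = factor(object$stage, levels = rev(STAGES))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$stage, group = 1)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a relative power spectrum
#'
#' @param object A `spectral_profile` from [stage_psd()].
#' @param ... Unused.
#' @return A ggplot of relative power against frequency, with the four band
#'   boundaries marked.
#' @method autoplot spectral_profile
#' @export
autoplot.spectral_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$freq_hz, y = .data$relative_power)) +
    ggplot2::geom_vline(xintercept = c(4, 8, 12), linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Frequency (Hz)", y = "Relative power",
      title = sprintf("%s spectrum (%d windows)",
                      attr(object, "stage"), attr(object, "n_windows"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot detected spindle events
#'
#' Event frequency against onset time, sized by amplitude and coloured by
#' subtype, with the 13 Hz slow/fast boundary drawn.
#'
#' @param object A `spindle_events` object from [detect_spindles()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spindle_events
#' @export
autoplot.spindle_events <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$onset_s / 60, y = .data$mean_freq_hz,
                               colour = .data$subtype,
                               size = .data$peak_amp_uv)) +
    ggplot2::geom_hline(yintercept = 13, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Onset (min)", y = "Mean frequency (Hz)",
                  colour = "Subtype", size = "Peak amp (µV)") +
    ggplot2::theme_minimal()
}

#' Plot a bin-by-bin correlation scan
#'
#' Correlation coefficient per frequency bin, with bins belonging to
#' significant Rüger areas highlighted.
#'
#' @param object A `pvalue_grid` from [binwise_scan()].
#' @param alpha Conventional significance level for the Rüger correction.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pvalue_grid
#' @export
autoplot.pvalue_grid <- function(object, alpha = 0.05, ...) {
  df <- flag_significant_bins(object, alpha)
  ggplot2::ggplot(as_tibble(df), ggplot2::aes(x = .data$freq_hz, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = as_tibble(df)[df$in_significant_area, ],
      colour = "red", size = 1.6
    ) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Pearson r",
                  title = "Bin-by-bin correlation scan (red: significant Rüger areas)") +
    ggplot2::theme_minimal()
}
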