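# broom-style tidiers for the package's result objects.

#' Tidy a spindle detection result
#'
#' @param x A `spindle_events` object from [detect_spindles()].
#' @param ... Unused.
#' @return Plain tibble of events.
#' @method tidy spindle_events
#' @export
tidy.spindle_events <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a spindle detection
#'
#' @param x A `spindle_events` object.
#' @param ... Unused.
#' @return Tibble with `n_events`, `n_slow`, `n_fast`, `nrem_minutes`,
#'   `density_slow`, `density_fast`, `n_iter`, `converged`.
#' @method glance spindle_events
#' @export
glance.spindle_events <- function(x, ...) {
  nm <- attr(x, "nrem_minutes")
  tibble(
    n_events = nrow(x),
    n_slow = sum(x$subtype == "slow"),
    n_fast = sum(x$subtype == "fast"),
    nrem_minutes = nm,
    density_slow = sum(x$subtype == "slow") / nm,
    density_fast = sum(x$subtype == "fast") / nm,
    n_iter = attr(x, "n_iter"),
    converged = attr(x, "converged")
  )
}

#' Tidy a cue schedule
#'
#' @param x A `cue_schedule` from [schedule_cues()].
#' @param ... Unused.
#' @return Tibble with one row per cue: `cue_time_s`, `cue_label`, `bout`.
#' @method tidy cue_schedule
#' @export
tidy.cue_schedule <- function(x, ...) {
  if (length(x$cue_times_s) == 0) {
    return(tibble(cue_time_s = numeric(0), cue_label = character(0),
                  bout = integer(0)))
  }
  bout <- findInterval(x$cue_times_s, x$bouts$start_s)
  tibble(cue_time_s = x$cue_times_s, cue_label = x$cue_label, bout = bout)
}

#' One-row summary of a cue schedule
#'
#' @param x A `cue_schedule`.
#' @param ... Unused.
#' @return Tibble with `n_cues`, `n_bouts`, `total_stim_s`, `first_cue_s`,
#'   `last_cue_s`.
#' @method glance cue_schedule
#' @export
glance.cue_schedule <- function(x, ...) {
  tibble(
    n_cues = length(x$cue_times_s),
    n_bouts = nrow(x$bouts),
    total_stim_s = x$total_stim_s,
    first_cue_s = if (length(x$cue_times_s)) min(x$cue_times_s) else NA_real_,
    last_cue_s = if (length(x$cue_times_s)) max(x$cue_times_s) else NA_real_
  )
}

#' Tidy a bin-by-bin scan
#'
#' @param x A `pvalue_grid` from [binwise_scan()].
#' @param ... Unused.
#' @return The grid with an `in_significant_area` flag (Rüger-corrected).
#' @method tidy pvalue_grid
#' @export
tidy.pvalue_grid <- function(x, ...) {
  as_tibble(flag_significant_bins(x))
}

#' One-row summary of a bin-by-bin scan
#'
#' @param x A `pvalue_grid`.
#' @param alpha Conventional significance level for the Rüger correction.
#' @param ... Unused.
#' @return Tibble with `n_bins`, `n_significant_bins`, `n_areas`,
#'   `n_significant_areas`.
#' @method glance pvalue_grid
#' @export
glance.pvalue_grid <- function(x, alpha = 0.05, ...) {
  areas <- ruger_areas(x, alpha)
  tibble(
    n_bins = nrow(x),
    n_significant_bins = sum(!is.na(x$p) & x$p < alpha),
    n_areas = nrow(areas),
    n_significant_areas = sum(areas$significant)
  )
}

#' One-row summary of a spectral profile
#'
#' @param x A `spectral_profile` from [stage_psd()].
#' @param ... Unused.
#' @return Tibble with `stage`, `n_windows` and the four band fractions.
#' @method glance spectral_profile
#' @export
glance.spectral_profile <- function(x, ...) {
  b <- band_powers(x)
  out <- tibble(stage = attr(x, "stage"), n_windows = attr(x, "n_windows"))
  out[b$band] <- as.list(b$relative_power)
  out
}
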