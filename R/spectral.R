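# Stage-restricted power spectral densities.
#
# 4-s Hann-tapered windows with 50% overlap give exact 0.25 Hz resolution;
# a "bin" is the single FFT coefficient at that frequency. The analysis grid
# runs 1.00-30.00 Hz inclusive: 117 bins.

#' Frequency grid of the spectral analysis
#'
#' @return Numeric vector of the 117 analysis frequencies, 1.00 to 30.00 Hz
#'   in 0.25 Hz steps.
#' @export
spectral_bins <- function() seq(1, 30, by = 0.25)

#' Frequency band definitions
#'
#' Half-open bands `[1,4)` delta, `[4,8)` theta, `[8,12)` alpha and closed
#' `[12,30]` beta, so the four bands partition the analysis grid (a shared
#' endpoint such as 4.00 Hz counts to the higher band).
#'
#' @return Tibble with `band`, `low_hz`, `high_hz`.
#' @export
spectral_bands <- function() {
  tibble(
    band = c("delta", "theta", "alpha", "beta"),
    low_hz = c(1, 4, 8, 12),
    high_hz = c(4, 8, 12, 30)
  )
}

band_of_bin <- function(freqs) {
  b <- spectral_bands()
  out <- rep(NA_character_, length(freqs))
  for (i in seq_len(nrow(b))) {
    sel <- freqs >= b$low_hz[i] & freqs < b$high_hz[i]
    out[sel] <- b$band[i]
  }
  out[freqs == 30] <- "beta" # closed upper edge of the grid
  out
}

# eligible 4-s window start times (seconds) for one stage: windows lie wholly
# inside a contiguous run of same-stage epochs, step 2 s, and are artifact-free
eligible_windows <- function(h, stage, artifacts, win_s = 4, step_s = 2) {
  es <- epoch_s(h)
  r <- rle(h$stage)
  run_end_ep <- cumsum(r$lengths)
  run_start_ep <- run_end_ep - r$lengths # 0-based epoch index of run start
  starts <- numeric(0)
  for (i in seq_along(r$values)) {
    if (r$values[i] != stage) next
    t0 <- run_start_ep[i] * es
    t1 <- run_end_ep[i] * es
    if (t1 - t0 < win_s) next
    starts <- c(starts, seq(t0, t1 - win_s, by = step_s))
  }
  if (length(starts) == 0) return(numeric(0))
  arts <- snap_artifacts(artifacts)
  starts[!intersects_artifact(starts, starts + win_s, arts)]
}

#' Stage-restricted relative power spectrum
#'
#' Computes the average power spectral density of one derived EEG signal over
#' all artifact-free 4-s windows (50% overlap, Hann taper, per-window mean
#' removal) lying wholly inside contiguous epochs of the requested stage,
#' then normalizes to relative power over the 1-30 Hz grid. No spectrum is
#' computed for the wake stage, whose muscle-tone artifacts make it
#' uninterpretable.
#'
#' @param x Numeric vector, a single-channel (derived) signal in microvolts.
#' @param h A [hypnogram()] covering the signal.
#' @param sample_rate_hz Sampling rate of `x` in Hz (must resolve 0.25 Hz
#'   bins on 4-s windows, i.e. `4 * sample_rate_hz` samples per window).
#' @param stage Stage to analyze: `"DROWSINESS"`, `"NREM"` or `"REM"`.
#' @param artifacts Optional artifact table; windows touching flagged 4-s
#'   subepochs are discarded.
#' @return A `spectral_profile` tibble with columns `freq_hz`,
#'   `relative_power` (sums to 1 over the 117 bins) and attributes `stage`
#'   and `n_windows`. When no eligible window exists, `relative_power` is
#'   all `NA` and `n_windows` is 0.
#' @export
stage_psd <- function(x, h, sample_rate_hz, stage, artifacts = NULL) {
  h <- as_hypnogram(h)
  if (stage == "WAKE") abort("no spectral analysis is defined for the wake stage")
  if (!stage %in% STAGES) abort(sprintf("unknown stage '%s'", stage))
  fs <- sample_rate_hz
  win_n <- round(4 * fs)
  if (abs(win_n - 4 * fs) > 1e-9) abort("4 * sample_rate_hz must be an integer")
  if (length(x) < nrow(h) * epoch_s(h) * fs - 1e-6) {
    abort("signal shorter than the hypnogram it is scored against")
  }

  starts <- eligible_windows(h, stage, artifacts)
  freqs <- spectral_bins()
  bin_idx <- as.integer(round(freqs * 4)) + 1L # FFT coefficient index

  if (length(starts) == 0) {
    return(new_spectral_profile(freqs, rep(NA_real_, length(freqs)), stage, 0L))
  }

  taper <- 0.5 * (1 - cos(2 * pi * seq_len(win_n) / (win_n + 1))) # Hann
  acc <- numeric(length(bin_idx))
  for (t0 in starts) {
    i0 <- round(t0 * fs) + 1L
    seg <- x[i0:(i0 + win_n - 1L)]
    seg <- (seg - mean(seg)) * taper
    pw <- Mod(fft(seg))^2
    acc <- acc + pw[bin_idx]
  }
  acc <- acc / length(starts)
  new_spectral_profile(freqs, acc / sum(acc), stage, length(starts))
}

new_spectral_profile <- function(freqs, rel, stage, n_windows) {
  out <- tibble(freq_hz = freqs, relative_power = rel)
  structure(out,
    stage = stage, n_windows = n_windows,
    class = c("spectral_profile", class(out))
  )
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf(
    "<spectral_profile: stage %s, %d window(s), %d bins>\n",
    attr(x, "stage"), attr(x, "n_windows"), nrow(x)
  ))
  NextMethod()
}

#' Relative power in the four canonical bands
#'
#' Sums relative bin power over the delta, theta, alpha and beta bands (see
#' [spectral_bands()] for the boundary convention). The four fractions sum
#' to 1 for any profile with at least one analysis window.
#'
#' @param profile A `spectral_profile` from [stage_psd()], or any data frame
#'   with `freq_hz` and `relative_power` columns.
#' @return Tibble with `band` and `relative_power` rows in delta-theta-
#'   alpha-beta order.
#' @export
band_powers <- function(profile) {
  bands <- band_of_bin(profile$freq_hz)
  out <- tibble(band = bands, relative_power = profile$relative_power) %>%
    group_by(.data$band) %>%
    summarise(relative_power = sum(.data$relative_power), .groups = "drop")
  out[match(spectral_bands()$band, out$band), ]
}
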