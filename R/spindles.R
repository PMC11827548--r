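# Adaptive amplitude-frequency sleep-spindle detection.
#
# Initial detections come from an envelope threshold over non-REM sigma-band
# activity; the detector then fits Gaussians (maximum likelihood) to the
# detected events' amplitudes and frequencies and re-detects using the
# fitted acceptance window, iterating until the event set is stable.

#' Detector parameters
#'
#' Defaults are a documented reconstruction of an adaptive amplitude-
#' frequency spindle detector, not a replication of any specific prior
#' implementation: sigma band 9-16 Hz, RMS envelope over a 0.125-s sliding
#' window, initial threshold at mean + 2 SD of the non-REM envelope,
#' acceptance at 2 SD of the fitted event distributions.
#'
#' @param sigma_band_hz Length-2 numeric, band-pass edges in Hz. Must
#'   straddle the 13 Hz slow/fast boundary.
#' @param envelope_window_s RMS envelope window in seconds.
#' @param init_threshold_k Initial threshold, in SD multiples above the mean
#'   non-REM envelope.
#' @param accept_z Acceptance half-width, in SD multiples of the fitted
#'   amplitude and frequency Gaussians.
#' @param min_freq_halfwidth_hz Floor on the frequency acceptance half-width
#'   in Hz. Guards against a degenerate window when the detected population
#'   is homogeneous (the fitted SD can shrink far below the ~0.5 Hz jitter
#'   of per-event zero-crossing frequency estimates).
#' @param min_amp_halfwidth_frac Floor on the amplitude acceptance
#'   half-width, as a fraction of the fitted mean amplitude, for the same
#'   reason.
#' @param extend_threshold_k Lower (boundary) threshold for re-detection, in
#'   SD multiples: once the acceptance window is fitted, candidate events are
#'   envelope runs above this lower threshold, so event extent and duration
#'   are measured at the burst's true boundaries rather than at the strict
#'   initial threshold.
#' @param max_iter Maximum refinement iterations.
#' @param convergence_tol Stop when the symmetric difference between
#'   successive event sets, divided by the current count, falls below this.
#' @param merge_gap_s Merge events separated by less than this gap.
#' @param min_duration_s Minimum spindle duration (0.5 s).
#' @return A `detector_params` list.
#' @export
detector_params <- function(sigma_band_hz = c(9, 16),
                            envelope_window_s = 0.125,
                            init_threshold_k = 2,
                            accept_z = 2,
                            min_freq_halfwidth_hz = 1,
                            min_amp_halfwidth_frac = 0.25,
                            extend_threshold_k = 0.25,
                            max_iter = 10,
                            convergence_tol = 0.01,
                            merge_gap_s = 0.1,
                            min_duration_s = 0.5) {
  if (!(sigma_band_hz[1] < 13 && 13 < sigma_band_hz[2])) {
    abort("sigma_band_hz must straddle the 13 Hz slow/fast boundary")
  }
  if (max_iter < 1) abort("max_iter must be >= 1")
  structure(
    list(
      sigma_band_hz = sigma_band_hz,
      envelope_window_s = envelope_window_s,
      init_threshold_k = init_threshold_k,
      accept_z = accept_z,
      min_freq_halfwidth_hz = min_freq_halfwidth_hz,
      min_amp_halfwidth_frac = min_amp_halfwidth_frac,
      extend_threshold_k = extend_threshold_k,
      max_iter = max_iter,
      convergence_tol = convergence_tol,
      merge_gap_s = merge_gap_s,
      min_duration_s = min_duration_s
    ),
    class = "detector_params"
  )
}

# zero-phase band-pass in the sigma band
sigma_bandpass <- function(x, fs, band) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# RMS envelope over a centred sliding window; edges use the available part
rms_envelope <- function(x, fs, window_s) {
  k <- max(3L, round(window_s * fs))
  cs <- cumsum(c(0, x^2))
  n <- length(x)
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

# mean intra-event oscillation frequency from zero-crossing intervals
zero_crossing_freq <- function(seg, fs) {
  s <- sign(seg)
  s[s == 0] <- 1
  zc <- which(diff(s) != 0)
  if (length(zc) < 2) return(NA_real_)
  mean_half_period <- (zc[length(zc)] - zc[1]) / (length(zc) - 1) / fs
  1 / (2 * mean_half_period)
}

# maximal runs of TRUE; returns list(start, end) in sample indices
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep], end = ends[keep])
}

run_count <- function(runs) length(runs$start)

run_subset <- function(runs, keep) {
  list(start = runs$start[keep], end = runs$end[keep])
}

# events in one run set with no overlapping partner in the other, summed
# both ways (event identity is by temporal overlap, since re-detection at a
# lower boundary threshold legitimately shifts onsets)
overlap_sym_diff <- function(a, b) {
  overlaps <- function(x, y) {
    vapply(seq_along(x$start), function(i) {
      any(x$start[i] <= y$end & x$end[i] >= y$start)
    }, logical(1))
  }
  if (run_count(a) == 0) return(run_count(b))
  if (run_count(b) == 0) return(run_count(a))
  sum(!overlaps(a, b)) + sum(!overlaps(b, a))
}

event_features <- function(runs, band_sig, env, fs, channel) {
  if (run_count(runs) == 0) {
    return(tibble(
      channel = character(0), onset_s = numeric(0), duration_s = numeric(0),
      mean_freq_hz = numeric(0), peak_amp_uv = numeric(0)
    ))
  }
  k <- run_count(runs)
  freq <- amp <- numeric(k)
  for (i in seq_len(k)) {
    a <- runs$start[i]
    b <- runs$end[i]
    e <- env[a:b]
    amp[i] <- max(e)
    # frequency from the event core (envelope >= half its peak), where the
    # oscillation dominates the background and zero crossings are clean
    core <- which(e >= amp[i] / 2)
    a2 <- a + core[1] - 1L
    b2 <- a + core[length(core)] - 1L
    freq[i] <- zero_crossing_freq(band_sig[a2:b2], fs)
  }
  tibble(
    channel = channel,
    onset_s = (runs$start - 1) / fs,
    duration_s = (runs$end - runs$start + 1) / fs,
    mean_freq_hz = freq,
    peak_amp_uv = amp
  )
}

merge_close_runs <- function(runs, gap_samples) {
  n <- run_count(runs)
  if (n < 2) return(runs)
  ord <- order(runs$start)
  rs <- runs$start[ord]
  re <- runs$end[ord]
  starts <- rs[1]
  ends <- re[1]
  for (i in 2:n) {
    k <- length(starts)
    if (rs[i] - ends[k] - 1 < gap_samples) {
      ends[k] <- max(ends[k], re[i])
    } else {
      starts <- c(starts, rs[i])
      ends <- c(ends, re[i])
    }
  }
  list(start = starts, end = ends)
}

#' Detect sleep spindles
#'
#' Runs the adaptive amplitude-frequency detector on one channel, restricted
#' to artifact-free non-REM samples. See [detector_params()] for the
#' algorithm's tunables. Events clipped by a non-REM run boundary are kept
#' if at least the minimum duration remains inside non-REM; events touching
#' artifact-flagged time are discarded (run finding operates only on valid
#' samples, so this holds by construction).
#'
#' @param x Numeric vector, single-channel EEG in microvolts.
#' @param h A [hypnogram()] covering the signal.
#' @param sample_rate_hz Sampling rate in Hz (>= 128 to resolve the sigma
#'   band).
#' @param params A [detector_params()] list.
#' @param artifacts Optional artifact table; flagged time (snapped to 4-s
#'   subepochs) is excluded from detection and from the non-REM envelope
#'   statistics.
#' @param channel Channel label recorded in the output.
#' @return A `spindle_events` tibble (`channel`, `onset_s`, `duration_s`,
#'   `mean_freq_hz`, `peak_amp_uv`, `subtype`) with attributes
#'   `nrem_minutes` (artifact-free), `n_iter` and `converged`.
#' @export
detect_spindles <- function(x, h, sample_rate_hz, params = detector_params(),
                            artifacts = NULL, channel = "Fz") {
  h <- as_hypnogram(h)
  fs <- sample_rate_hz
  if (fs < 128) abort("sample rate below 128 Hz cannot resolve the spindle band")
  n <- length(x)
  es <- epoch_s(h)

  # valid = inside an NREM epoch and outside snapped artifact intervals
  nrem_mask <- logical(n)
  for (i in which(h$stage == "NREM")) {
    a <- round((i - 1) * es * fs) + 1L
    b <- min(n, round(i * es * fs))
    if (b >= a) nrem_mask[a:b] <- TRUE
  }
  arts <- snap_artifacts(artifacts)
  valid <- nrem_mask & !artifact_sample_mask(arts, n, fs)
  nrem_minutes <- sum(valid) / fs / 60
  if (nrem_minutes < 1) {
    abort("less than one artifact-free non-REM minute; cannot detect spindles")
  }

  band_sig <- sigma_bandpass(x, fs, params$sigma_band_hz)
  env <- rms_envelope(band_sig, fs, params$envelope_window_s)
  env_valid <- env
  env_valid[!valid] <- -Inf # runs break at NREM boundaries and artifacts

  mu <- mean(env[valid])
  sdev <- sd(env[valid])
  min_len <- round(params$min_duration_s * fs)
  gap_len <- round(params$merge_gap_s * fs)

  detect_runs <- function(threshold) {
    runs <- true_runs(env_valid > threshold)
    runs <- merge_close_runs(runs, gap_len)
    run_subset(runs, runs$end - runs$start + 1 >= min_len)
  }

  # initial detections: strict amplitude criterion only
  runs <- detect_runs(mu + params$init_threshold_k * sdev)
  if (run_count(runs) == 0) {
    warn("no initial spindle detections; returning an empty event list")
    return(new_spindle_events(
      classify_spindles(event_features(runs, band_sig, env, fs, channel)),
      nrem_minutes, 0L, TRUE, params
    ))
  }

  # refinement: fit the event amplitude/frequency Gaussians, then re-detect
  # over candidate runs at the lower boundary threshold, accepting events
  # whose peak amplitude and mean frequency fall inside a fitted window.
  # Windows are fitted separately for the slow (< 13 Hz) and fast (>= 13 Hz)
  # event populations present among the current detections: a single
  # Gaussian over a bimodal slow+fast mixture centres on the dominant
  # subtype and extinguishes the rarer one.
  low_thr <- mu + params$extend_threshold_k * sdev
  cand <- detect_runs(low_thr)
  cand_feats <- event_features(cand, band_sig, env, fs, channel)

  fit_window <- function(amp, freq) {
    amp_mu <- mean(amp)
    freq_mu <- mean(freq)
    list(
      amp_mu = amp_mu,
      amp_hw = max(params$accept_z * sd(amp),
                   params$min_amp_halfwidth_frac * amp_mu),
      freq_mu = freq_mu,
      freq_hw = max(params$accept_z * sd(freq), params$min_freq_halfwidth_hz)
    )
  }

  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(params$max_iter)) {
    feats <- event_features(runs, band_sig, env, fs, channel)
    ok <- is.finite(feats$mean_freq_hz)
    if (sum(ok) < 2) break # too few events to refit
    windows <- list()
    for (fast in c(FALSE, TRUE)) {
      sel <- ok & ((feats$mean_freq_hz >= 13) == fast)
      if (sum(sel) >= 2 && sd(feats$peak_amp_uv[sel]) > 0 &&
            sd(feats$mean_freq_hz[sel]) > 0) {
        windows[[length(windows) + 1]] <-
          fit_window(feats$peak_amp_uv[sel], feats$mean_freq_hz[sel])
      }
    }
    if (length(windows) == 0) break

    accept <- rep(FALSE, nrow(cand_feats))
    for (w in windows) {
      accept <- accept | (
        is.finite(cand_feats$mean_freq_hz) &
          abs(cand_feats$peak_amp_uv - w$amp_mu) <= w$amp_hw &
          abs(cand_feats$mean_freq_hz - w$freq_mu) <= w$freq_hw
      )
    }
    new_runs <- run_subset(cand, accept)

    n_iter <- iter
    sym_diff <- overlap_sym_diff(runs, new_runs)
    runs <- new_runs
    if (run_count(runs) == 0) break
    if (sym_diff / run_count(runs) < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }

  events <- classify_spindles(event_features(runs, band_sig, env, fs, channel))
  new_spindle_events(events, nrem_minutes, n_iter, converged, params)
}

new_spindle_events <- function(events, nrem_minutes, n_iter, converged, params) {
  structure(events,
    nrem_minutes = nrem_minutes, n_iter = n_iter, converged = converged,
    detector_params = params,
    class = c("spindle_events", class(as_tibble(events)))
  )
}

#' Classify spindles as slow or fast
#'
#' Applies the common 13 Hz boundary: fast spindles have mean frequency
#' >= 13 Hz (boundary inclusive), slow spindles < 13 Hz.
#'
#' @param events Tibble with a `mean_freq_hz` column.
#' @return The events with a `subtype` column (`"slow"`/`"fast"`).
#' @examples
#' classify_spindles(tibble::tibble(mean_freq_hz = c(12.99, 13, 14.2)))
#' @export
classify_spindles <- function(events) {
  events$subtype <- ifelse(events$mean_freq_hz >= 13, "fast", "slow")
  events
}

#' Spindle density
#'
#' Events per minute of (artifact-free) non-REM sleep, computed per channel
#' and subtype.
#'
#' @param events A `spindle_events` tibble from [detect_spindles()], or any
#'   tibble with `channel` and `subtype` columns.
#' @param nrem_minutes Density denominator in minutes. Defaults to the
#'   `nrem_minutes` attribute carried by [detect_spindles()] output.
#' @param subtype Optional filter: `"slow"`, `"fast"` or `NULL` for both
#'   subtypes (one row each).
#' @param channel Optional channel filter.
#' @return Tibble with `channel`, `subtype`, `n_events`, `nrem_minutes`,
#'   `events_per_min`.
#' @export
spindle_density <- function(events, nrem_minutes = attr(events, "nrem_minutes"),
                            subtype = NULL, channel = NULL) {
  if (is.null(nrem_minutes) || !is.finite(nrem_minutes) || nrem_minutes <= 0) {
    abort("nrem_minutes must be positive")
  }
  ev <- as_tibble(events)
  channels <- channel %||% unique(ev$channel) %||% character(0)
  if (length(channels) == 0) channels <- NA_character_
  subtypes <- subtype %||% c("slow", "fast")
  grid <- tidyr::expand_grid(channel = channels, subtype = subtypes)
  grid %>%
    mutate(
      n_events = purrr::map2_int(
        .data$channel, .data$subtype,
        ~ sum(ev$channel == .x & ev$subtype == .y)
      ),
      nrem_minutes = nrem_minutes,
      events_per_min = .data$n_events / nrem_minutes
    )
}

#' Within-subject averaged (trait) spindle density
#'
#' The unweighted mean of per-recording densities for one subject, pooled
#' across that subject's recordings (e.g. adaptation and TMR). Averaged
#' density approximates the stable interindividual trait and reduces
#' per-recording measurement error.
#'
#' @param densities Numeric vector of per-recording densities (events/min),
#'   or a data frame with an `events_per_min` column.
#' @return The mean density, events/min.
#' @examples
#' averaged_density(c(2, 1))
#' @export
averaged_density <- function(densities) {
  if (is.data.frame(densities)) densities <- densities$events_per_min
  if (length(densities) == 0) abort("at least one recording is required")
  mean(densities)
}
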