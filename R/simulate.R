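# Synthetic polysomnography and behavior with ground truth.
#
# The generator emulates the study design it is meant to exercise: 2-h
# afternoon-nap recordings at 1,024 Hz on the Fz/Cz/F7/F8 montage, 20-s
# scored epochs over wake/drowsiness/NREM/REM, sigma-band spindle bursts
# injected into non-REM at known density, manual-style 4-s artifact flags,
# non-REM-gated cue logs, and 15 baseline + 15 test behavioral trials per
# dog with a configurable post-sleep latency reduction.

#' Simulation parameters
#'
#' Defaults describe the study conditions being emulated; see the package
#' vignette for the rationale behind each value.
#'
#' @param n_dogs Number of subjects (16).
#' @param recording_minutes Recording length (120, a 2-h nap).
#' @param epoch_s Offline scoring epoch (20 s).
#' @param sample_rate_hz Sampling rate (1,024 Hz; must be >= 128).
#' @param channels EEG channel labels.
#' @param spindle_channels Channels receiving spindle injections.
#' @param stage_dwell_means Named numeric, mean stage dwell times in
#'   minutes for the semi-Markov hypnogram chain.
#' @param stage_transitions 4x4 row-stochastic matrix of embedded-chain
#'   transition probabilities (rows/cols in [STAGES] order, zero diagonal).
#' @param background_rms_uv RMS of the 1/f EEG background, microvolts.
#' @param spindle_density_slow,spindle_density_fast Injected densities,
#'   events per artifact-free non-REM minute.
#' @param spindle_freq_means,spindle_freq_sds Named (`slow`, `fast`) Gaussian
#'   parameters of per-event spindle frequency, Hz.
#' @param spindle_amp_factor Peak burst amplitude as a multiple of the
#'   background RMS.
#' @param spindle_dur_range Burst duration range in seconds (minimum 0.5, a
#'   spindle's minimum duration).
#' @param artifact_rate Fraction of 4-s subepochs flagged as artifact.
#' @param cueing_latency_effect Named (`correct`, `incorrect`) multiplicative
#'   post-sleep latency reduction factors (test latencies are divided by
#'   these).
#' @param accuracy_logit_params Named (`baseline`, `cued_shift`) log-odds of
#'   a correct choice; the shift applies to cued trials post-sleep.
#' @param latency_meanlog,latency_sdlog Lognormal baseline latency
#'   parameters (log-seconds).
#' @param latency_floor_s Lower bound on any latency (physical plausibility).
#' @param density_effect_corr Correlation, on the latent scale, between a
#'   dog's trait fast-spindle density and its correct-trial latency effect
#'   (0 = independent).
#' @param density_dog_sd,latency_effect_dog_sd Log-scale between-dog SDs of
#'   trait density and of the correct-trial latency factor.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_dogs = 16,
                       recording_minutes = 120,
                       epoch_s = 20,
                       sample_rate_hz = 1024,
                       channels = c("Fz", "Cz", "F7", "F8"),
                       spindle_channels = c("Fz", "Cz"),
                       stage_dwell_means = c(WAKE = 4, DROWSINESS = 5,
                                             NREM = 12, REM = 3.5),
                       stage_transitions = default_stage_transitions(),
                       background_rms_uv = 20,
                       spindle_density_slow = 2,
                       spindle_density_fast = 2,
                       spindle_freq_means = c(slow = 11, fast = 14.5),
                       spindle_freq_sds = c(slow = 0.4, fast = 0.4),
                       spindle_amp_factor = 3,
                       spindle_dur_range = c(0.5, 1.5),
                       artifact_rate = 0.02,
                       cueing_latency_effect = c(correct = 2, incorrect = 1.25),
                       accuracy_logit_params = c(baseline = 0, cued_shift = 0),
                       latency_meanlog = log(5),
                       latency_sdlog = 0.45,
                       latency_floor_s = 0.3,
                       density_effect_corr = 0,
                       density_dog_sd = 0.6,
                       latency_effect_dog_sd = 0.5) {
  if (recording_minutes <= 0) abort("recording_minutes must be positive")
  if (spindle_dur_range[1] < 0.5) abort("minimum spindle duration is 0.5 s")
  if (spindle_density_slow < 0 || spindle_density_fast < 0) {
    abort("spindle densities must be non-negative")
  }
  if (artifact_rate < 0 || artifact_rate > 1) abort("artifact_rate must be in [0, 1]")
  if (abs(density_effect_corr) > 1) abort("density_effect_corr must be in [-1, 1]")
  structure(as.list(environment()), class = "sim_params")
}

#' Default embedded-chain stage transitions
#'
#' Wake always passes through drowsiness, and drowsiness leads to non-REM
#' with high probability, reproducing the wake -> drowsiness -> non-REM
#' entry into sleep typical of a canine nap.
#'
#' @return 4x4 row-stochastic matrix over [STAGES].
#' @export
default_stage_transitions <- function() {
  m <- matrix(0, 4, 4, dimnames = list(STAGES, STAGES))
  m["WAKE", "DROWSINESS"] <- 1
  m["DROWSINESS", c("NREM", "WAKE")] <- c(0.85, 0.15)
  m["NREM", c("REM", "DROWSINESS", "WAKE")] <- c(0.45, 0.35, 0.2)
  m["REM", c("NREM", "DROWSINESS", "WAKE")] <- c(0.5, 0.25, 0.25)
  m
}

#' Stationary stage occupancy of the hypnogram chain
#'
#' Long-run fraction of time in each stage implied by the semi-Markov
#' parameters: the embedded chain's stationary distribution weighted by mean
#' dwell times. Used as the reference when checking simulated hypnograms.
#'
#' @param params A [sim_params()] list.
#' @return Named numeric over [STAGES], summing to 1.
#' @export
stationary_occupancy <- function(params) {
  P <- params$stage_transitions[STAGES, STAGES]
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi_embed <- Re(e$vectors[, i])
  pi_embed <- pi_embed / sum(pi_embed)
  occ <- pi_embed * params$stage_dwell_means[STAGES]
  occ / sum(occ)
}

#' Generate a hypnogram
#'
#' Semi-Markov chain on 20-s epochs: geometric dwell times with the
#' configured means, embedded transitions from `stage_transitions`, always
#' starting awake (so wake precedes the first drowsiness, and under the
#' default transitions drowsiness precedes the first non-REM epoch).
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed.
#' @return A [hypnogram()].
#' @export
gen_hypnogram <- function(params = sim_params(), seed = 1) {
  if (params$recording_minutes <= 0) abort("recording_minutes must be positive")
  n_epochs <- ceiling(params$recording_minutes * 60 / params$epoch_s)
  withr::local_seed(seed)
  dwell_s <- params$stage_dwell_means[STAGES] * 60
  P <- params$stage_transitions[STAGES, STAGES]
  labels <- character(0)
  stage <- "WAKE"
  while (length(labels) < n_epochs) {
    if (!is.finite(dwell_s[stage])) {
      dwell_ep <- n_epochs - length(labels)
    } else {
      p <- min(1, params$epoch_s / dwell_s[stage])
      dwell_ep <- 1L + rgeom(1, p)
    }
    labels <- c(labels, rep(stage, dwell_ep))
    stage <- sample(STAGES, 1, prob = P[stage, ])
  }
  hypnogram(labels[seq_len(n_epochs)], epoch_s = params$epoch_s)
}

# 1/f amplitude-shaped Gaussian noise, unit RMS
pink_noise <- function(n, fs) {
  white <- rnorm(n)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f) # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 0.1))
  x <- Re(fft(fft(white) * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

stage_oscillation <- function(stage, tt) {
  osc <- switch(stage,
    DROWSINESS = 0.8 * sin(2 * pi * 7 * tt),
    NREM = 1.5 * sin(2 * pi * 1.5 * tt),
    REM = 0.4 * sin(2 * pi * 6 * tt),
    WAKE = 0
  )
  # slow amplitude modulation so oscillations wax and wane
  osc * (0.7 + 0.3 * sin(2 * pi * 0.05 * tt))
}

#' Generate a spindle-bearing EEG recording for one hypnogram
#'
#' Per stage, the signal is a 1/f background plus a stage-characteristic
#' amplitude-modulated oscillation (drowsiness: 7 Hz alpha-theta; non-REM:
#' 1.5 Hz delta; REM: low-amplitude 6 Hz). Hann-windowed sigma-band bursts
#' are injected into artifact-free non-REM at the configured slow and fast
#' densities, wholly inside single non-REM epochs and never overlapping
#' each other or artifact-flagged time. Artifact subepochs receive a
#' large-amplitude transient. Samples are quantized to float32 so written
#' signal files round-trip exactly.
#'
#' @param h A [hypnogram()].
#' @param params A [sim_params()] list.
#' @param seed Integer seed.
#' @return List with `recording` (an [eeg_recording()]), `spindles`
#'   (ground-truth event tibble: `channel`, `onset_s`, `duration_s`,
#'   `freq_hz`, `amplitude_uv`, `subtype`), `artifacts` (interval tibble)
#'   and `nrem_minutes` (artifact-free non-REM minutes used for the
#'   injected-count denominators).
#' @export
gen_eeg <- function(h, params = sim_params(), seed = 1) {
  h <- as_hypnogram(h)
  if (nrow(h) == 0) abort("hypnogram must be non-empty")
  fs <- params$sample_rate_hz
  if (fs < 128) abort("sample rate below 128 Hz cannot resolve the spindle band")
  withr::local_seed(seed)
  es <- epoch_s(h)
  dur_s <- nrow(h) * es
  n <- round(dur_s * fs)

  # artifact flags on the 4-s rejection grid
  n_sub <- floor(dur_s / 4)
  flagged <- which(runif(n_sub) < params$artifact_rate)
  artifacts <- tibble(start_s = (flagged - 1) * 4, end_s = flagged * 4)

  # artifact-free non-REM minutes: denominator for injected counts
  nrem_min <- stage_minutes(h, "NREM", artifacts = artifacts)

  # per-epoch second offsets of each stage
  stage_of_sample <- rep(h$stage, each = round(es * fs))[seq_len(n)]
  tt <- (seq_len(n) - 1) / fs

  osc <- numeric(n)
  for (st in c("DROWSINESS", "NREM", "REM")) {
    idx <- stage_of_sample == st
    if (any(idx)) osc[idx] <- stage_oscillation(st, tt[idx])
  }

  rms <- params$background_rms_uv
  samples <- matrix(0, length(params$channels), n,
    dimnames = list(params$channels, NULL)
  )
  ev_channel <- ev_subtype <- character(0)
  ev_onset <- ev_dur <- ev_freq <- ev_amp <- numeric(0)
  nrem_epochs <- which(h$stage == "NREM")

  for (ch in params$channels) {
    x <- rms * pink_noise(n, fs) + rms * osc
    if (ch %in% params$spindle_channels && length(nrem_epochs) > 0 && nrem_min > 0) {
      placed_on <- placed_off <- numeric(0)
      for (subtype in c("slow", "fast")) {
        dens <- if (subtype == "slow") params$spindle_density_slow else params$spindle_density_fast
        n_ev <- round(dens * nrem_min)
        for (k in seq_len(n_ev)) {
          pl <- place_burst(h, artifacts, placed_on, placed_off, params)
          if (is.null(pl)) abort("could not place a spindle burst; too little non-REM")
          freq <- rnorm(1, params$spindle_freq_means[subtype],
                        params$spindle_freq_sds[subtype])
          amp <- params$spindle_amp_factor * rms
          i0 <- round(pl$onset_s * fs) + 1L
          len <- round(pl$dur_s * fs)
          tb <- (seq_len(len) - 1) / fs
          taper <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
          x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
            amp * taper * sin(2 * pi * freq * tb + runif(1, 0, 2 * pi))
          placed_on <- c(placed_on, pl$onset_s)
          placed_off <- c(placed_off, pl$onset_s + pl$dur_s)
          ev_channel <- c(ev_channel, ch)
          ev_onset <- c(ev_onset, pl$onset_s)
          ev_dur <- c(ev_dur, pl$dur_s)
          ev_freq <- c(ev_freq, freq)
          ev_amp <- c(ev_amp, amp)
          ev_subtype <- c(ev_subtype, subtype)
        }
      }
    }
    # movement-like transient in flagged subepochs
    for (i in seq_len(nrow(artifacts))) {
      a <- round(artifacts$start_s[i] * fs) + 1L
      b <- min(n, round(artifacts$end_s[i] * fs))
      x[a:b] <- x[a:b] + 8 * rms * sin(2 * pi * 0.5 * tt[a:b])
    }
    samples[ch, ] <- float32_quantize(x)
  }

  spindles <- tibble(
    channel = ev_channel, onset_s = ev_onset, duration_s = ev_dur,
    freq_hz = ev_freq, amplitude_uv = ev_amp, subtype = ev_subtype
  )
  list(
    recording = eeg_recording(samples, fs, params$channels),
    spindles = spindles,
    artifacts = artifacts,
    nrem_minutes = nrem_min
  )
}

# find an onset/duration wholly inside one artifact-free stretch of a single
# NREM epoch, clear of already-placed bursts
place_burst <- function(h, artifacts, placed_on, placed_off, params,
                        margin_s = 0.3) {
  es <- epoch_s(h)
  nrem_epochs <- which(h$stage == "NREM")
  for (attempt in seq_len(1000)) {
    ep <- nrem_epochs[sample.int(length(nrem_epochs), 1)]
    dur <- runif(1, params$spindle_dur_range[1], params$spindle_dur_range[2])
    t0 <- (ep - 1) * es + runif(1, 0, es - dur)
    t1 <- t0 + dur
    if (intersects_artifact(t0 - margin_s, t1 + margin_s, artifacts)) next
    if (length(placed_on) > 0 &&
        any(t0 - margin_s < placed_off & t1 + margin_s > placed_on)) next
    return(list(onset_s = t0, dur_s = dur))
  }
  NULL
}

# fixed semirandom baiting order: five 3-trial blocks, each location baited
# exactly five times per 15-trial phase, never the same location twice in a row
.bait_blocks <- c("ABC", "ACB", "CAB", "CBA", "BAC")
.bait_sequence <- function() {
  loc <- strsplit(paste(.bait_blocks, collapse = ""), "")[[1]]
  unname(c(A = "left", B = "center", C = "right")[loc])
}

#' Generate behavioral trials
#'
#' Per dog: 15 baseline + 15 test trials whose baited locations cycle the
#' fixed semirandom block order (each location baited exactly five times per
#' phase). One side (left/right, counterbalanced by dog-index parity) is the
#' cued side. Correctness is Bernoulli on the configured log-odds;
#' latencies are lognormal, with post-sleep latencies divided by the
#' correct/incorrect latency-effect factors (floored at
#' `latency_floor_s`).
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed.
#' @param per_dog Optional tibble (`dog_id`, `correct_factor`,
#'   `incorrect_factor`) of per-dog latency effects; defaults to the shared
#'   `cueing_latency_effect` values.
#' @return Trial tibble: `dog_id`, `phase`, `trial_index`, `cue_class`,
#'   `correct`, `latency_s`.
#' @export
gen_behavior <- function(params = sim_params(), seed = 1, per_dog = NULL) {
  withr::local_seed(seed)
  baits <- .bait_sequence()
  out <- vector("list", params$n_dogs)
  for (d in seq_len(params$n_dogs)) {
    dog_id <- sprintf("dog%02d", d)
    cued_side <- if (d %% 2 == 1) "left" else "right"
    cf <- params$cueing_latency_effect[["correct"]]
    icf <- params$cueing_latency_effect[["incorrect"]]
    if (!is.null(per_dog)) {
      row <- per_dog[per_dog$dog_id == dog_id, ]
      if (nrow(row) == 1) {
        cf <- row$correct_factor
        icf <- row$incorrect_factor
      }
    }
    phases <- list()
    for (phase in c("baseline", "test")) {
      cue_class <- ifelse(
        baits == "center", "center",
        paste0(ifelse(baits == cued_side, "cued_", "uncued_"), baits)
      )
      logit <- params$accuracy_logit_params[["baseline"]] +
        params$accuracy_logit_params[["cued_shift"]] *
          (phase == "test") * is_cued(cue_class)
      correct <- rbinom(15, 1, plogis(logit))
      lat <- rlnorm(15, params$latency_meanlog, params$latency_sdlog)
      if (phase == "test") {
        lat <- lat / ifelse(correct == 1, cf, icf)
      }
      lat <- pmax(lat, params$latency_floor_s)
      phases[[phase]] <- tibble(
        dog_id = dog_id, phase = phase, trial_index = 1:15,
        cue_class = cue_class, correct = correct, latency_s = lat
      )
    }
    out[[d]] <- bind_rows(phases)
  }
  bind_rows(out)
}

#' Generate a full synthetic study
#'
#' Per dog: one adaptation recording (no cues) and one TMR recording with a
#' non-REM-gated cue log, plus behavior trials and per-dog ground truth.
#' When `density_effect_corr` is nonzero, each dog's trait fast-spindle
#' density and correct-trial latency factor are drawn from a correlated
#' latent Gaussian pair, injecting a known density-learning association for
#' end-to-end recovery tests.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, all files (float32+JSON
#'   signals, hypnogram/artifact/cue-log CSVs, trials and ground-truth
#'   CSVs) are written there, one subdirectory per dog.
#' @return A `tmr_study` list: `params`, `dogs` (per-dog list of
#'   `adaptation`/`tmr` session bundles), `trials`, and `truth` (per-dog
#'   tibble with `dog_id`, `cued_side`, `trait_density_fast`,
#'   `trait_density_slow`, `correct_factor`, `incorrect_factor`,
#'   `latency_effect_ratio`).
#' @export
gen_study <- function(params = sim_params(), seed = 1, out_dir = NULL) {
  if (params$n_dogs < 1) abort("n_dogs must be >= 1")
  withr::local_seed(seed)
  rho <- params$density_effect_corr
  z1 <- rnorm(params$n_dogs)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(params$n_dogs)
  truth <- tibble(
    dog_id = sprintf("dog%02d", seq_len(params$n_dogs)),
    cued_side = ifelse(seq_len(params$n_dogs) %% 2 == 1, "left", "right"),
    trait_density_fast = params$spindle_density_fast * exp(params$density_dog_sd * z1),
    trait_density_slow = params$spindle_density_slow,
    correct_factor = params$cueing_latency_effect[["correct"]] *
      exp(params$latency_effect_dog_sd * z2),
    incorrect_factor = params$cueing_latency_effect[["incorrect"]]
  )
  truth$latency_effect_ratio <- truth$correct_factor / truth$incorrect_factor

  dogs <- vector("list", params$n_dogs)
  for (d in seq_len(params$n_dogs)) {
    dog_seed <- (seed + 104729 * d) %% 2147483647L
    dogs[[d]] <- gen_dog_sessions(params, truth[d, ], dog_seed)
  }
  names(dogs) <- truth$dog_id

  trials <- gen_behavior(
    params, seed = (seed + 7919) %% 2147483647L,
    per_dog = truth
  )

  study <- structure(
    list(params = params, dogs = dogs, trials = trials, truth = truth),
    class = "tmr_study"
  )
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

gen_dog_sessions <- function(params, truth_row, dog_seed) {
  p_dog <- params
  p_dog$spindle_density_fast <- truth_row$trait_density_fast
  p_dog$spindle_density_slow <- truth_row$trait_density_slow
  sessions <- list()
  for (i in 1:2) {
    session <- c("adaptation", "tmr")[i]
    h <- gen_hypnogram(params, seed = dog_seed + i)
    eeg <- gen_eeg(h, p_dog, seed = dog_seed + 10 + i)
    cue_log <- tibble(cue_time_s = numeric(0), cue_label = character(0))
    if (session == "tmr") {
      online <- online_stage_stream(h)
      sched <- schedule_cues(online, cue_label = truth_row$cued_side)
      cue_log <- tibble(
        cue_time_s = sched$cue_times_s,
        cue_label = rep(sched$cue_label, length(sched$cue_times_s))
      )
    }
    sessions[[session]] <- list(
      hypnogram = h, recording = eeg$recording, artifacts = eeg$artifacts,
      spindles = eeg$spindles, nrem_minutes = eeg$nrem_minutes,
      cue_log = cue_log
    )
  }
  sessions
}

#' Resample an offline hypnogram to the online 30-s staging stream
#'
#' The online staging runs on 30-s epochs independent of the 20-s offline
#' scoring; here the online estimate is taken as the offline stage at each
#' online epoch's midpoint.
#'
#' @param h A [hypnogram()] (20-s epochs).
#' @param online_epoch_s Online epoch length (30 s).
#' @return Character vector of online stage estimates.
#' @export
online_stage_stream <- function(h, online_epoch_s = 30) {
  h <- as_hypnogram(h)
  es <- epoch_s(h)
  total_s <- nrow(h) * es
  n_online <- floor(total_s / online_epoch_s)
  mid <- (seq_len(n_online) - 0.5) * online_epoch_s
  h$stage[pmin(floor(mid / es) + 1, nrow(h))]
}

# ---- study serialization ---------------------------------------------------

#' Write a synthetic study to disk
#'
#' One subdirectory per dog with `adaptation`/`tmr` float32+JSON signal
#' pairs, hypnogram, artifact and cue-log CSVs, ground-truth spindle CSVs,
#' plus study-level `trials.csv` and `truth.csv`.
#'
#' @param study A `tmr_study` from [gen_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (dog_id in names(study$dogs)) {
    ddir <- file.path(dir, dog_id)
    dir.create(ddir, showWarnings = FALSE)
    for (session in c("adaptation", "tmr")) {
      s <- study$dogs[[dog_id]][[session]]
      stem <- file.path(ddir, session)
      write_recording(s$recording, stem)
      write_hypnogram(s$hypnogram, paste0(stem, "_hypnogram.csv"))
      write_artifacts(s$artifacts, paste0(stem, "_artifacts.csv"))
      readr::write_csv(s$cue_log, paste0(stem, "_cues.csv"))
      readr::write_csv(s$spindles, paste0(stem, "_truth_spindles.csv"))
    }
  }
  readr::write_csv(study$trials, file.path(dir, "trials.csv"))
  readr::write_csv(study$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read a synthetic study written by [write_study()]
#'
#' @param dir Study directory.
#' @param epoch_s Offline epoch length in seconds.
#' @return A `tmr_study`-shaped list (without `params`).
#' @export
read_study <- function(dir, epoch_s = 20) {
  dog_dirs <- sort(list.dirs(dir, recursive = FALSE))
  dogs <- purrr::map(dog_dirs, function(ddir) {
    purrr::map(
      c(adaptation = "adaptation", tmr = "tmr"),
      function(session) {
        stem <- file.path(ddir, session)
        list(
          hypnogram = read_hypnogram(paste0(stem, "_hypnogram.csv"), epoch_s),
          recording = read_recording(stem),
          artifacts = read_artifacts(paste0(stem, "_artifacts.csv")),
          spindles = readr::read_csv(paste0(stem, "_truth_spindles.csv"),
            col_types = readr::cols()
          ),
          cue_log = read_cue_log(paste0(stem, "_cues.csv"))
        )
      }
    )
  })
  names(dogs) <- basename(dog_dirs)
  list(
    dogs = dogs,
    trials = read_trials(file.path(dir, "trials.csv")),
    truth = readr::read_csv(file.path(dir, "truth.csv"),
      col_types = readr::cols()
    )
  )
}
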