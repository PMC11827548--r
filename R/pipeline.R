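# End-to-end helpers tying the synthetic study to the analysis modules.

#' Per-recording and trait spindle densities for a whole study
#'
#' Runs the spindle detector on every recording of a [gen_study()] bundle
#' (or an equivalently shaped list) and returns per-session fast and slow
#' densities together with each dog's within-subject averaged (trait)
#' density. Sessions without at least one artifact-free non-REM minute give
#' `NA` densities; the trait mean uses the available sessions.
#'
#' @param study A `tmr_study` list.
#' @param channel Channel to detect on (default `"Fz"`).
#' @param params [detector_params()] for the detector.
#' @return List of two tibbles: `sessions` (`dog_id`, `session`,
#'   `density_fast`, `density_slow`, `nrem_minutes`) and `traits`
#'   (`dog_id`, `trait_density_fast`, `trait_density_slow`).
#' @export
study_spindle_densities <- function(study, channel = "Fz",
                                    params = detector_params()) {
  fs <- study$params$sample_rate_hz
  rows <- list()
  for (dog_id in names(study$dogs)) {
    for (session in names(study$dogs[[dog_id]])) {
      s <- study$dogs[[dog_id]][[session]]
      res <- tryCatch(
        {
          ev <- suppressWarnings(detect_spindles(
            derive_channel(s$recording, channel), s$hypnogram, fs,
            params = params, artifacts = s$artifacts, channel = channel
          ))
          nm <- attr(ev, "nrem_minutes")
          c(sum(ev$subtype == "fast") / nm, sum(ev$subtype == "slow") / nm, nm)
        },
        error = function(e) c(NA_real_, NA_real_, NA_real_)
      )
      rows[[length(rows) + 1]] <- tibble(
        dog_id = dog_id, session = session,
        density_fast = res[1], density_slow = res[2], nrem_minutes = res[3]
      )
    }
  }
  sessions <- bind_rows(rows)
  traits <- sessions %>%
    group_by(.data$dog_id) %>%
    summarise(
      trait_density_fast = mean(.data$density_fast, na.rm = TRUE),
      trait_density_slow = mean(.data$density_slow, na.rm = TRUE),
      .groups = "drop"
    )
  list(sessions = sessions, traits = traits)
}

#' Study conditions for replicate recovery simulations
#'
#' The reduced problem size used for Monte-Carlo validation of the full
#' pipeline: 16 dogs, 6-minute recordings sampled at 128 Hz on a single
#' spindle-bearing channel, a nap structure that reaches non-REM quickly
#' (dwell means: wake 0.5, drowsiness 1, non-REM 8, REM 1.5 min), and a
#' latent correlation of 0.6 between each dog's trait fast-spindle density
#' and its correct-trial latency effect. These sizes keep hundreds of
#' replicate studies tractable while leaving every pipeline stage
#' (generation, detection, density, behavior statistics, correlation)
#' exercised at realistic signal-to-noise; the vignette discusses the
#' choices.
#'
#' @param density_effect_corr Injected latent density-effect correlation.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` list.
#' @export
recovery_sim_params <- function(density_effect_corr = 0.6, ...) {
  sim_params(
    n_dogs = 16, recording_minutes = 6, sample_rate_hz = 128,
    channels = "Fz", spindle_channels = "Fz",
    stage_dwell_means = c(WAKE = 0.5, DROWSINESS = 1, NREM = 8, REM = 1.5),
    density_effect_corr = density_effect_corr,
    ...
  )
}

#' Replicate-study recovery of the density-learning association
#'
#' For each replicate: generate a full synthetic study, run the spindle
#' detector on every recording, average each dog's fast-spindle density
#' across its two recordings (the trait density), compute each dog's
#' relative latency reduction from the trial table, and correlate the two
#' across dogs. The distribution of the resulting Pearson r over replicates
#' measures how reliably the pipeline recovers the injected association.
#'
#' @param n_reps Number of replicate studies.
#' @param params Study conditions, by default [recovery_sim_params()].
#' @param seed Base seed; replicate i uses `seed + i`.
#' @return Tibble with `rep`, `r` (pipeline-estimated correlation) and
#'   `r_truth` (correlation between the generator's true per-dog trait
#'   density and latency-effect ratio).
#' @export
density_effect_recovery <- function(n_reps = 200,
                                    params = recovery_sim_params(),
                                    seed = 1) {
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    st <- gen_study(params, seed = (seed + i) %% 2147483647L)
    traits <- study_spindle_densities(st)$traits
    bs <- behavior_summary(st$trials)
    df <- dplyr::left_join(traits, bs, by = "dog_id")
    out[[i]] <- tibble(
      rep = i,
      r = stats::cor(df$trait_density_fast, df$relative_latency_reduction,
                     use = "complete.obs"),
      r_truth = stats::cor(st$truth$trait_density_fast,
                           st$truth$latency_effect_ratio)
    )
  }
  bind_rows(out)
}

#' Type-I error of the bin-by-bin scan under the null
#'
#' Simulates studies in which the outcome is independent of the spectra
#' (both standard normal) and returns the per-bin rejection rate of the
#' scan at the given alpha, which should match alpha.
#'
#' @param n_reps Number of simulated null studies.
#' @param n_subjects Subjects per study.
#' @param n_bins Frequency bins per spectrum (default the 117-bin grid).
#' @param alpha Nominal level.
#' @param seed Seed.
#' @return The overall rejection proportion across replicates and bins.
#' @export
scan_type1_error <- function(n_reps = 1000, n_subjects = 16,
                             n_bins = length(spectral_bins()),
                             alpha = 0.05, seed = 1) {
  withr::local_seed(seed)
  rej <- 0L
  tot <- 0L
  for (i in seq_len(n_reps)) {
    m <- matrix(rnorm(n_subjects * n_bins), n_subjects, n_bins)
    y <- rnorm(n_subjects)
    g <- binwise_scan(m, y, freqs = seq_len(n_bins))
    rej <- rej + sum(g$p < alpha, na.rm = TRUE)
    tot <- tot + sum(!is.na(g$p))
  }
  rej / tot
}
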