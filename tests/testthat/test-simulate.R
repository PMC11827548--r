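# Synthetic hypnograms, EEG, behavior and study bundles.

test_that("hypnogram generation is deterministic and validated", {
  p <- sim_params(recording_minutes = 30)
  h1 <- gen_hypnogram(p, seed = 7)
  h2 <- gen_hypnogram(p, seed = 7)
  expect_identical(h1$stage, h2$stage)
  expect_equal(nrow(h1), 30 * 60 / 20)
  expect_equal(h1$stage[1], "WAKE") # recordings start awake

  expect_error(gen_hypnogram(sim_params(recording_minutes = -1)), "positive")
})

test_that("all dwell mass on wake gives an all-wake hypnogram", {
  p <- sim_params(
    recording_minutes = 10,
    stage_dwell_means = c(WAKE = Inf, DROWSINESS = 1, NREM = 1, REM = 1)
  )
  h <- gen_hypnogram(p, seed = 3)
  expect_true(all(h$stage == "WAKE"))
})

test_that("wake precedes drowsiness which precedes non-REM under defaults", {
  p <- sim_params(recording_minutes = 60)
  for (s in 1:20) {
    h <- gen_hypnogram(p, seed = s)
    first_d <- match("DROWSINESS", h$stage)
    first_n <- match("NREM", h$stage)
    if (!is.na(first_d)) expect_gt(first_d, 1)
    if (!is.na(first_n)) expect_lt(first_d, first_n)
  }
})

test_that("simulated stage occupancy tracks the chain's stationary occupancy", {
  p <- sim_params(recording_minutes = 120)
  target <- stationary_occupancy(p)
  props <- matrix(0, 200, 4, dimnames = list(NULL, STAGES))
  for (s in 1:200) {
    h <- gen_hypnogram(p, seed = 1000 + s)
    for (st in STAGES) props[s, st] <- mean(h$stage == st)
  }
  got <- colMeans(props)
  # finite recordings start awake, so occupancy is estimated to +-10 points
  expect_true(all(abs(got - target) < 0.10))
})

test_that("zero densities give an empty ground-truth spindle list", {
  p <- test_sim_params(spindle_density_slow = 0, spindle_density_fast = 0)
  h <- nrem_fixture_hypnogram(1)
  e <- gen_eeg(h, p, seed = 1)
  expect_equal(nrow(e$spindles), 0)
})

test_that("injected event count is density times artifact-free non-REM minutes", {
  p <- test_sim_params(
    spindle_density_slow = 0, spindle_density_fast = 4, artifact_rate = 0
  )
  h <- hypnogram(rep("N", 30)) # exactly 10 min NREM
  e <- gen_eeg(h, p, seed = 2)
  fz <- e$spindles[e$spindles$channel == "Fz", ]
  expect_equal(nrow(fz), 40)
  expect_true(all(fz$subtype == "fast"))
  # wholly inside single NREM epochs
  expect_true(all(floor(fz$onset_s / 20) == floor((fz$onset_s + fz$duration_s) / 20)))
  expect_true(all(fz$duration_s >= 0.5))
})

test_that("ground-truth spindles avoid wake, REM and artifact intervals", {
  p <- test_sim_params(artifact_rate = 0.05)
  h <- hypnogram(rep(c("W", "N", "N", "R", "N", "N"), 3))
  e <- gen_eeg(h, p, seed = 9)
  sp <- e$spindles
  ep0 <- floor(sp$onset_s / 20) + 1
  expect_true(all(h$stage[ep0] == "NREM"))
  expect_false(any(caninetmr:::intersects_artifact(
    sp$onset_s, sp$onset_s + sp$duration_s, e$artifacts
  )))
})

test_that("injected bursts raise sigma-band RMS at least two-fold", {
  p <- test_sim_params(artifact_rate = 0, spindle_density_fast = 3,
                       spindle_density_slow = 2)
  h <- hypnogram(rep("N", 15))
  e <- gen_eeg(h, p, seed = 4)
  fs <- p$sample_rate_hz
  x <- derive_channel(e$recording, "Fz")
  band <- caninetmr:::sigma_bandpass(x, fs, c(11, 16))
  inside <- logical(length(x))
  fz <- e$spindles[e$spindles$channel == "Fz", ]
  for (i in seq_len(nrow(fz))) {
    a <- round(fz$onset_s[i] * fs) + 1
    b <- round((fz$onset_s[i] + fz$duration_s[i]) * fs)
    inside[a:b] <- TRUE
  }
  rms_in <- sqrt(mean(band[inside]^2))
  rms_out <- sqrt(mean(band[!inside]^2))
  expect_gte(rms_in / rms_out, 2)
})

test_that("eeg generation is deterministic and rejects low sample rates", {
  p <- test_sim_params()
  h <- nrem_fixture_hypnogram(1)
  e1 <- gen_eeg(h, p, seed = 5)
  e2 <- gen_eeg(h, p, seed = 5)
  expect_identical(e1$recording$samples, e2$recording$samples)
  expect_identical(e1$spindles, e2$spindles)
  expect_error(gen_eeg(h, sim_params(sample_rate_hz = 100), seed = 1), "128")
})

test_that("behavior tables have the fixed semirandom bait structure", {
  p <- sim_params(n_dogs = 6)
  tr <- gen_behavior(p, seed = 8)
  expect_equal(nrow(tr), 6 * 30)
  counts <- tr %>%
    dplyr::count(.data$dog_id, .data$phase)
  expect_true(all(counts$n == 15))
  # each location baited exactly five times per 15-trial phase
  side <- dplyr::case_when(
    tr$cue_class == "center" ~ "center",
    grepl("left", tr$cue_class) ~ "left",
    TRUE ~ "right"
  )
  loc_counts <- tibble::tibble(dog = tr$dog_id, phase = tr$phase, side = side) %>%
    dplyr::count(.data$dog, .data$phase, .data$side)
  expect_true(all(loc_counts$n == 5))
  # cued side alternates with dog parity; exactly one cued side per dog
  cued <- tr %>%
    dplyr::filter(.data$cue_class %in% c("cued_left", "cued_right")) %>%
    dplyr::distinct(.data$dog_id, .data$cue_class)
  expect_equal(nrow(cued), 6)
  expect_equal(cued$cue_class, rep(c("cued_left", "cued_right"), 3))
})

test_that("unit latency factors give pre/post ratios near one", {
  p <- sim_params(
    n_dogs = 200,
    cueing_latency_effect = c(correct = 1, incorrect = 1),
    latency_effect_dog_sd = 0
  )
  bs <- behavior_summary(gen_behavior(p, seed = 10))
  expect_equal(mean(bs$lat_reduction_correct, na.rm = TRUE), 1, tolerance = 0.05)
  expect_equal(mean(bs$lat_reduction_incorrect, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("configured latency factors produce the expected relative reduction", {
  p <- sim_params(
    n_dogs = 500,
    cueing_latency_effect = c(correct = 2, incorrect = 1.25),
    latency_effect_dog_sd = 0
  )
  bs <- behavior_summary(gen_behavior(p, seed = 11))
  x <- bs$relative_latency_reduction
  # the generative ratio is 2 / 1.25 = 1.6; the per-dog estimator (a ratio
  # of ratios of ~7-trial means) is median-unbiased but its mean carries a
  # positive Jensen bias of ~+0.10 at lognormal sigma 0.45 (value frozen
  # from a 12,000-dog Monte-Carlo of the generative model)
  expect_equal(median(x, na.rm = TRUE), 1.6, tolerance = 0.1)
  expect_equal(mean(x, na.rm = TRUE), 1.70, tolerance = 0.1)
})

test_that("a study bundle has the right shape and determinism", {
  p <- test_sim_params(n_dogs = 3, recording_minutes = 4,
                       stage_dwell_means = c(WAKE = 0.5, DROWSINESS = 1,
                                             NREM = 6, REM = 1))
  st <- gen_study(p, seed = 12)
  expect_length(st$dogs, 3)
  expect_equal(nrow(st$trials), 3 * 30)
  expect_equal(nrow(st$truth), 3)
  for (d in st$dogs) {
    expect_named(d, c("adaptation", "tmr"))
    expect_equal(nrow(d$adaptation$cue_log), 0) # no cues during adaptation
  }
  st2 <- gen_study(p, seed = 12)
  expect_identical(st$trials, st2$trials)
  expect_identical(st$dogs[[2]]$tmr$recording$samples,
                   st2$dogs[[2]]$tmr$recording$samples)
  expect_error(gen_study(sim_params(n_dogs = 0)), "n_dogs")
})

test_that("a written study round-trips bit-exactly", {
  p <- test_sim_params(n_dogs = 2, recording_minutes = 4,
                       stage_dwell_means = c(WAKE = 0.5, DROWSINESS = 1,
                                             NREM = 6, REM = 1))
  dir <- withr::local_tempdir()
  st <- gen_study(p, seed = 13, out_dir = dir)
  back <- read_study(dir)
  expect_equal(names(back$dogs), names(st$dogs))
  for (id in names(st$dogs)) {
    for (ss in c("adaptation", "tmr")) {
      a <- st$dogs[[id]][[ss]]
      b <- back$dogs[[id]][[ss]]
      expect_identical(b$recording$samples, a$recording$samples)
      expect_equal(b$hypnogram$stage, a$hypnogram$stage)
      expect_equal(as.data.frame(b$artifacts), as.data.frame(a$artifacts))
      expect_equal(as.data.frame(b$cue_log), as.data.frame(a$cue_log))
      expect_equal(as.data.frame(b$spindles), as.data.frame(a$spindles),
                   tolerance = 1e-12)
    }
  }
  expect_equal(as.data.frame(back$trials), as.data.frame(st$trials),
               tolerance = 1e-12)
})
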