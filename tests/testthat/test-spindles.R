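# Adaptive spindle detection, classification and density.

fs <- 256

test_that("slow/fast classification uses an inclusive 13 Hz boundary", {
  ev <- classify_spindles(tibble::tibble(mean_freq_hz = c(12.99, 13, 14.2)))
  expect_equal(ev$subtype, c("slow", "fast", "fast"))
})

test_that("density arithmetic is count over non-REM minutes", {
  ev <- tibble::tibble(
    channel = "Fz",
    subtype = c(rep("fast", 8), rep("slow", 2))
  )
  d <- spindle_density(ev, nrem_minutes = 4, subtype = "fast", channel = "Fz")
  expect_equal(d$events_per_min, 2)
  expect_equal(d$n_events, 8L)
  d0 <- spindle_density(ev[0, ], nrem_minutes = 4, subtype = "fast", channel = "Fz")
  expect_equal(d0$events_per_min, 0)
  # doubling the denominator halves the density
  d2 <- spindle_density(ev, nrem_minutes = 8, subtype = "fast", channel = "Fz")
  expect_equal(d2$events_per_min, d$events_per_min / 2)
  expect_error(spindle_density(ev, nrem_minutes = 0), "positive")
})

test_that("averaged (trait) density is the unweighted mean across recordings", {
  expect_equal(averaged_density(c(2, 1)), 1.5)
  expect_equal(averaged_density(3.7), 3.7)
  expect_equal(averaged_density(c(0.5, 2, 1)), averaged_density(c(1, 0.5, 2)))
  expect_error(averaged_density(numeric(0)), "at least one")
})

test_that("a single injected burst is found once, as slow, with sane duration", {
  set.seed(21)
  h <- hypnogram(rep("N", 9)) # 3 min NREM
  n <- nrow(h) * 20 * fs
  x <- 20 * caninetmr:::pink_noise(n, fs)
  rms <- sqrt(mean(x^2))
  len <- round(1 * fs)
  tb <- (seq_len(len) - 1) / fs
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
  i0 <- round(60 * fs)
  x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] +
    4 * rms * taper * sin(2 * pi * 11 * tb)
  ev <- detect_spindles(x, h, fs, channel = "Fz")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$subtype, "slow")
  expect_gte(ev$duration_s, 0.5)
  expect_lte(ev$duration_s, 1.5)
  expect_lt(abs(ev$onset_s - 60), 0.5)
  expect_equal(ev$mean_freq_hz, 11, tolerance = 1)
})

test_that("injected fast bursts are recovered with high recall, none in wake", {
  set.seed(22)
  # 5 min NREM plus wake bracketing
  h <- hypnogram(c("W", "W", rep("N", 15), "W"))
  n <- nrow(h) * 20 * fs
  x <- 20 * caninetmr:::pink_noise(n, fs)
  rms <- sqrt(mean(x^2))
  onsets <- 40 + (0:19) * 14.5 # 20 bursts inside the NREM block
  for (t0 in onsets) {
    len <- round(1 * fs)
    tb <- (seq_len(len) - 1) / fs
    taper <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
    i0 <- round(t0 * fs)
    x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] +
      3 * rms * taper * sin(2 * pi * 13.5 * tb)
  }
  ev <- detect_spindles(x, h, fs, channel = "Fz")
  matched <- purrr::map_lgl(onsets, function(t0)
    any(ev$onset_s < t0 + 1 & ev$onset_s + ev$duration_s > t0))
  expect_gte(sum(matched), 18)
  expect_true(all(ev$subtype == "fast"))
  # every event wholly inside the NREM block (epochs 2..16, i.e. 40-340 s)
  expect_true(all(ev$onset_s >= 40 & ev$onset_s + ev$duration_s <= 340))
})

test_that("spindle-free 1/f noise yields zero detections", {
  set.seed(23)
  h <- hypnogram(rep("N", 15))
  x <- 20 * caninetmr:::pink_noise(nrow(h) * 20 * fs, fs)
  ev <- suppressWarnings(detect_spindles(x, h, fs))
  expect_equal(nrow(ev), 0)
})

test_that("detection is deterministic and respects artifacts and stage bounds", {
  p <- test_sim_params(spindle_density_slow = 1, spindle_density_fast = 2,
                       artifact_rate = 0.05)
  h <- nrem_fixture_hypnogram()
  e <- gen_eeg(h, p, seed = 31)
  x <- derive_channel(e$recording, "Fz")
  ev1 <- detect_spindles(x, h, fs, artifacts = e$artifacts, channel = "Fz")
  ev2 <- detect_spindles(x, h, fs, artifacts = e$artifacts, channel = "Fz")
  expect_identical(as.data.frame(ev1), as.data.frame(ev2))

  # SpindleEvent invariants
  expect_true(all(ev1$duration_s >= 0.5))
  expect_true(all((ev1$mean_freq_hz >= 13) == (ev1$subtype == "fast")))
  arts <- snap_artifacts(e$artifacts)
  expect_false(any(caninetmr:::intersects_artifact(
    ev1$onset_s, ev1$onset_s + ev1$duration_s, arts
  )))
  # events inside NREM epochs only
  ep0 <- floor(ev1$onset_s / 20) + 1
  ep1 <- ceiling((ev1$onset_s + ev1$duration_s) / 20)
  for (i in seq_len(nrow(ev1))) {
    expect_true(all(h$stage[ep0[i]:ep1[i]] == "NREM"))
  }
})

test_that("raising the initial threshold never increases initial detections", {
  p <- test_sim_params(spindle_density_slow = 1, spindle_density_fast = 2)
  h <- nrem_fixture_hypnogram()
  e <- gen_eeg(h, p, seed = 41)
  x <- derive_channel(e$recording, "Fz")
  counts <- purrr::map_int(c(1.5, 2, 2.5, 3, 4), function(k) {
    ev <- suppressWarnings(detect_spindles(
      x, h, fs, artifacts = e$artifacts,
      params = detector_params(init_threshold_k = k, max_iter = 1,
                               convergence_tol = 0, extend_threshold_k = k)
    ))
    nrow(ev)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("detection requires non-REM sleep", {
  x <- rnorm(3 * 20 * fs)
  expect_error(detect_spindles(x, hypnogram(c("W", "W", "R")), fs), "non-REM")
  expect_error(detect_spindles(x, hypnogram(c("N", "N", "N")), 100), "128")
})
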