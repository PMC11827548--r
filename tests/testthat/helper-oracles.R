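# Independent brute-force oracles used to cross-check the package's
# implementations, deliberately written with different algorithms.

# Rüger areas by explicit left-to-right walking (no rle), counting with
# simple loops.
brute_ruger <- function(p, alpha = 0.05) {
  n <- length(p)
  sig <- !is.na(p) & p < alpha
  areas <- list()
  i <- 1
  while (i <= n) {
    if (!sig[i]) {
      i <- i + 1
      next
    }
    j <- i
    while (j < n && sig[j + 1]) j <- j + 1
    ps <- p[i:j]
    nb <- j - i + 1
    n_half <- 0
    n_third <- 0
    for (q in ps) {
      if (q < alpha / 2) n_half <- n_half + 1
      if (q < alpha / 3) n_third <- n_third + 1
    }
    areas[[length(areas) + 1]] <- list(
      start = i, end = j, n_bins = nb,
      n_half = n_half, n_third = n_third,
      significant = (n_half >= nb / 2) && (n_third >= nb / 3)
    )
    i <- j + 1
  }
  areas
}

# eligible 4-s/50%-overlap window count by brute force over every candidate
# start on the 2-s grid
brute_window_count <- function(stages, stage, artifacts, epoch_s = 20,
                               win_s = 4, step_s = 2) {
  total_s <- length(stages) * epoch_s
  arts <- caninetmr::snap_artifacts(artifacts)
  count <- 0
  t0 <- 0
  while (t0 + win_s <= total_s) {
    secs <- seq(t0, t0 + win_s - 1)
    eps <- floor(secs / epoch_s) + 1
    ok <- all(stages[unique(eps)] == stage)
    if (ok && nrow(arts) > 0) {
      for (k in seq_len(nrow(arts))) {
        if (t0 < arts$end_s[k] && t0 + win_s > arts$start_s[k]) ok <- FALSE
      }
    }
    # window must also not straddle a run boundary: all epochs same stage
    # AND contiguous in the same run (same-stage epochs are enough since a
    # run is a maximal same-stage stretch)
    if (ok) count <- count + 1
    t0 <- t0 + step_s
  }
  count
}

# short NREM-rich hypnogram used across signal tests
nrem_fixture_hypnogram <- function(n_blocks = 3) {
  hypnogram(rep(c("W", "N", "N", "N", "N", "N"), n_blocks))
}

# test-scale simulation parameters: short recording, modest rate
test_sim_params <- function(...) {
  defaults <- list(
    recording_minutes = 6, sample_rate_hz = 256,
    channels = c("Fz", "Cz"), spindle_channels = "Fz"
  )
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
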