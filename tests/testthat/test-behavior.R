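# Cueing benefit, latency reduction, relative latency reduction, scan.

mk_trials <- function(base_correct, test_correct,
                      base_lat = NULL, test_lat = NULL,
                      cue_class = "cued_left") {
  nb <- length(base_correct)
  nt <- length(test_correct)
  tibble::tibble(
    dog_id = "dog01",
    phase = c(rep("baseline", nb), rep("test", nt)),
    trial_index = c(seq_len(nb), seq_len(nt)),
    cue_class = cue_class,
    correct = c(base_correct, test_correct),
    latency_s = c(base_lat %||% rep(5, nb), test_lat %||% rep(5, nt))
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cueing benefit is the cued-trial accuracy difference", {
  tr <- mk_trials(c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 0))
  expect_equal(cueing_benefit(tr), 0.4)
  expect_equal(cueing_benefit(mk_trials(c(1, 0), c(0, 1))), 0)
  expect_equal(cueing_benefit(mk_trials(rep(0, 5), rep(1, 5))), 1)
  # uncued trials are ignored
  tr2 <- dplyr::bind_rows(
    mk_trials(c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 0)),
    mk_trials(rep(0, 5), rep(0, 5), cue_class = "uncued_right")
  )
  expect_equal(cueing_benefit(tr2), 0.4)
  # no cued trials in a phase -> missing
  expect_true(is.na(cueing_benefit(mk_trials(1, 1, cue_class = "center"))))
})

test_that("latency reduction is the ratio of per-class phase means", {
  tr <- mk_trials(c(1, 1), c(1, 1), base_lat = c(5, 7), test_lat = c(2, 4))
  expect_equal(latency_reduction(tr, 1L), 2)
  expect_true(is.na(latency_reduction(tr, 0L)))
  tr_same <- mk_trials(c(1, 1), c(1, 1), base_lat = c(4, 6), test_lat = c(6, 4))
  expect_equal(latency_reduction(tr_same, 1L), 1)
  tr_slow <- mk_trials(1, 1, base_lat = 3, test_lat = 6)
  expect_equal(latency_reduction(tr_slow, 1L), 0.5)
})

test_that("relative latency reduction divides the class ratios and is scale
           invariant", {
  tr <- dplyr::bind_rows(
    mk_trials(c(1, 1), c(1, 1), base_lat = c(6, 6), test_lat = c(3, 3)),
    mk_trials(c(0, 0), c(0, 0), base_lat = c(5, 5), test_lat = c(4, 4))
  )
  expect_equal(relative_latency_reduction(tr, quiet = TRUE), 2 / 1.25)
  tr_scaled <- dplyr::mutate(tr, latency_s = latency_s * 2)
  expect_equal(relative_latency_reduction(tr_scaled, quiet = TRUE),
               relative_latency_reduction(tr, quiet = TRUE))
  # equal reductions -> 1
  tr_eq <- dplyr::bind_rows(
    mk_trials(1, 1, base_lat = 6, test_lat = 3),
    mk_trials(0, 0, base_lat = 8, test_lat = 4)
  )
  expect_equal(relative_latency_reduction(tr_eq, quiet = TRUE), 1)
  # a class missing in one phase -> NA with a message
  tr_na <- mk_trials(c(1, 0), c(1, 1), base_lat = c(5, 5), test_lat = c(3, 3))
  expect_message(out <- relative_latency_reduction(tr_na), "excluded")
  expect_true(is.na(out))
})

test_that("behavior_summary gives one row per dog with all four statistics", {
  p <- sim_params(n_dogs = 4)
  tr <- gen_behavior(p, seed = 5)
  bs <- behavior_summary(tr)
  expect_equal(nrow(bs), 4)
  expect_setequal(
    names(bs),
    c("dog_id", "cueing_benefit", "lat_reduction_correct",
      "lat_reduction_incorrect", "relative_latency_reduction")
  )
  # agrees with the per-dog functions
  d1 <- tr[tr$dog_id == "dog01", ]
  expect_equal(bs$cueing_benefit[1], cueing_benefit(d1))
  expect_equal(bs$relative_latency_reduction[1],
               relative_latency_reduction(d1, quiet = TRUE))
})

test_that("binwise scan matches cor.test bin by bin", {
  set.seed(13)
  m <- matrix(rnorm(12 * 20), 12, 20)
  y <- rnorm(12)
  g <- binwise_scan(m, y, freqs = seq_len(20))
  for (j in c(1, 7, 20)) {
    ct <- cor.test(m[, j], y)
    expect_equal(g$r[j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(g$p[j], ct$p.value, tolerance = 1e-12)
  }
  expect_true(all(g$n == 12))
})

test_that("binwise scan is exact for proportional outcomes and antisymmetric
           under sign flips", {
  set.seed(14)
  m <- matrix(rnorm(10 * 8), 10, 8)
  y <- 3 * m[, 5] + 2
  g <- binwise_scan(m, y, freqs = seq_len(8))
  expect_equal(g$r[5], 1, tolerance = 1e-12)
  g_neg <- binwise_scan(m, -y, freqs = seq_len(8))
  expect_equal(g_neg$r, -g$r, tolerance = 1e-12)
  expect_equal(g_neg$p, g$p, tolerance = 1e-10)
})

test_that("binwise scan handles missing subjects bin-wise and degenerate bins", {
  set.seed(15)
  m <- matrix(rnorm(8 * 4), 8, 4)
  m[1:2, 2] <- NA
  m[, 3] <- 5 # zero variance
  y <- rnorm(8)
  g <- binwise_scan(m, y, freqs = 1:4)
  expect_equal(g$n, c(8L, 6L, 8L, 8L))
  expect_true(is.na(g$r[3]) && is.na(g$p[3]))
  ct <- cor.test(m[3:8, 2], y[3:8])
  expect_equal(g$r[2], unname(ct$estimate), tolerance = 1e-12)
  expect_error(binwise_scan(m[1:3, ], y[1:3], freqs = 1:4), "at least 4")
})

test_that("type-I error of the scan is nominal under the null", {
  set.seed(16)
  n_rep <- 200
  rej <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    m <- matrix(rnorm(16 * 40), 16, 40)
    y <- rnorm(16)
    g <- binwise_scan(m, y, freqs = seq_len(40))
    rej[i] <- mean(g$p < 0.05)
  }
  expect_equal(mean(rej), 0.05, tolerance = 0.02)
})
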