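# The nine sleep-macrostructure variables exported from a scored hypnogram.

#' Sleep macrostructure summary
#'
#' Computes the nine standard macrostructure variables from a 20-s-epoch
#' hypnogram. Because the wake-to-sleep transition in dogs passes through a
#' scored drowsiness stage, sleep latency and wakefulness after sleep onset
#' (WASO) each come in two flavours: anchored at the first drowsiness epoch
#' (`sleep_latency1_min`, `waso1_min`) and at the first non-REM epoch
#' (`sleep_latency2_min`, `waso2_min`).
#'
#' Sleep efficiency is time asleep relative to total recording length, where
#' "asleep" includes drowsiness by default (`drowsiness_is_sleep = TRUE`);
#' set it to `FALSE` to count only NREM + REM as sleep. WASO counts WAKE
#' epochs strictly after the anchor epoch; drowsiness is never counted as
#' wake. Relative stage durations are percentages of the total recording.
#'
#' Stages that never occur yield `NA` for the corresponding latency and WASO
#' (a recording with no REM is common in short daytime naps).
#'
#' @param h A [hypnogram()], a data frame with a `stage` column, or a
#'   character vector of stage labels.
#' @param epoch_s Epoch length override in seconds.
#' @param drowsiness_is_sleep Count drowsiness epochs as sleep in the
#'   efficiency numerator? Default `TRUE`.
#' @return A one-row tibble with columns `sleep_efficiency`, `relative_wake`,
#'   `sleep_latency1_min`, `sleep_latency2_min`, `waso1_min`, `waso2_min`,
#'   `relative_drowsiness`, `relative_nrem`, `relative_rem` (percentages and
#'   minutes).
#' @examples
#' macrostructure(c("W", "W", "D", "N", "N", "R", "N", "W", "W"))
#' @export
macrostructure <- function(h, epoch_s = NULL, drowsiness_is_sleep = TRUE) {
  h <- as_hypnogram(h, epoch_s)
  es <- epoch_s(h)
  n <- nrow(h)
  st <- h$stage

  n_wake <- sum(st == "WAKE")
  n_drow <- sum(st == "DROWSINESS")
  n_nrem <- sum(st == "NREM")
  n_rem <- sum(st == "REM")

  sleep_stages <- if (drowsiness_is_sleep) {
    c("DROWSINESS", "NREM", "REM")
  } else {
    c("NREM", "REM")
  }
  efficiency <- 100 * sum(st %in% sleep_stages) / n

  first_d <- match("DROWSINESS", st) # NA if absent
  first_n <- match("NREM", st)

  latency_min <- function(first) {
    if (is.na(first)) NA_real_ else (first - 1) * es / 60
  }
  waso_min <- function(first) {
    if (is.na(first)) return(NA_real_)
    sum(st[seq_len(n) > first] == "WAKE") * es / 60
  }

  tibble(
    sleep_efficiency = efficiency,
    relative_wake = 100 * n_wake / n,
    sleep_latency1_min = latency_min(first_d),
    sleep_latency2_min = latency_min(first_n),
    waso1_min = waso_min(first_d),
    waso2_min = waso_min(first_n),
    relative_drowsiness = 100 * n_drow / n,
    relative_nrem = 100 * n_nrem / n,
    relative_rem = 100 * n_rem / n
  )
}
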