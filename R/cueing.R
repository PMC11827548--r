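# Non-REM-gated cue scheduling: a deterministic replay of the online TMR
# protocol over a stream of 30-s stage estimates.

#' Cue-scheduling parameters
#'
#' @param online_epoch_s Online staging epoch length in seconds (30).
#' @param consec_nrem_epochs_required Consecutive non-REM epochs needed
#'   before a cueing bout may start (2, i.e. ~1 min of stable non-REM).
#' @param inter_cue_s Interval between cue onsets within a bout (5 s).
#' @param stim_cap_s Cumulative stimulation cap across bouts in seconds
#'   (300, the protocol's ~5 min of stimulation).
#' @param resume_after_arousal May a new bout start after an arousal aborts
#'   one, once the non-REM criterion is met again? Default `TRUE`.
#' @return A `cue_params` list.
#' @export
cue_params <- function(online_epoch_s = 30,
                       consec_nrem_epochs_required = 2,
                       inter_cue_s = 5,
                       stim_cap_s = 300,
                       resume_after_arousal = TRUE) {
  vals <- c(online_epoch_s, consec_nrem_epochs_required, inter_cue_s, stim_cap_s)
  if (any(vals <= 0)) abort("all cue parameters must be positive")
  structure(
    list(
      online_epoch_s = online_epoch_s,
      consec_nrem_epochs_required = consec_nrem_epochs_required,
      inter_cue_s = inter_cue_s,
      stim_cap_s = stim_cap_s,
      resume_after_arousal = resume_after_arousal
    ),
    class = "cue_params"
  )
}

#' Schedule TMR cues over an online stage stream
#'
#' Replays the online cueing rule: after `consec_nrem_epochs_required`
#' consecutive non-REM epochs, a bout starts and the cue fires every
#' `inter_cue_s` seconds (first cue at bout start) for as long as the stream
#' stays in non-REM. Any non-NREM epoch aborts the bout instantly — no cue
#' is emitted in that epoch. New bouts may start once the non-REM criterion
#' is met afresh, until the cumulative stimulation cap is reached (each cue
#' accounts for one inter-cue interval of stimulation).
#'
#' @param stages Character vector of online 30-s stage estimates (canonical
#'   labels or one-letter codes).
#' @param params A [cue_params()] list.
#' @param cue_label Label of the played cue (e.g. the nonword's side).
#' @return A `cue_schedule` object: list with `cue_label`, `cue_times_s`,
#'   `bouts` (tibble `start_s`, `end_s`, `n_cues`) and `total_stim_s`.
#' @examples
#' s <- schedule_cues(c("W", "D", rep("N", 10)))
#' length(s$cue_times_s) # 48 cues at 120, 125, ..., 355 s
#' @export
schedule_cues <- function(stages, params = cue_params(), cue_label = "cue") {
  if (length(stages) == 0) abort("stage stream must be non-empty")
  stages <- as.character(stages)
  if (all(stages %in% .stage_codes)) stages <- stage_from_code(stages)
  es <- params$online_epoch_s

  cue_times <- numeric(0)
  bouts <- list()
  consec <- 0L
  in_bout <- FALSE
  bout_start <- NA_real_
  bout_cues <- 0L
  stim_s <- 0
  capped <- FALSE

  close_bout <- function(end_s) {
    if (in_bout && bout_cues > 0) {
      bouts[[length(bouts) + 1]] <<- tibble(
        start_s = bout_start, end_s = end_s, n_cues = bout_cues
      )
    }
    in_bout <<- FALSE
    bout_cues <<- 0L
  }

  for (i in seq_along(stages)) {
    t0 <- (i - 1) * es
    if (stages[i] != "NREM") {
      close_bout(t0)
      consec <- 0L
      if (!params$resume_after_arousal && length(bouts) > 0) capped <- TRUE
      next
    }
    consec <- consec + 1L
    if (!in_bout && !capped && consec >= params$consec_nrem_epochs_required + 1L) {
      # criterion met at the end of the previous epoch; bout starts here
      in_bout <- TRUE
      bout_start <- t0
    }
    if (in_bout) {
      # cue grid anchored at bout start, spanning this NREM epoch
      for (tc in seq(t0, t0 + es - params$inter_cue_s, by = params$inter_cue_s)) {
        off <- tc - bout_start
        if (abs(off %% params$inter_cue_s) > 1e-9) next
        if (stim_s + params$inter_cue_s > params$stim_cap_s) {
          capped <- TRUE
          break
        }
        cue_times <- c(cue_times, tc)
        bout_cues <- bout_cues + 1L
        stim_s <- stim_s + params$inter_cue_s
      }
      if (capped) {
        close_bout(if (bout_cues > 0) cue_times[length(cue_times)] + params$inter_cue_s else t0)
      }
    }
  }
  close_bout(length(stages) * es)

  structure(
    list(
      cue_label = cue_label,
      cue_times_s = cue_times,
      bouts = if (length(bouts)) bind_rows(bouts) else
        tibble(start_s = numeric(0), end_s = numeric(0), n_cues = integer(0)),
      total_stim_s = stim_s,
      params = params
    ),
    class = "cue_schedule"
  )
}

#' @export
print.cue_schedule <- function(x, ...) {
  cat(sprintf(
    "<cue_schedule '%s': %d cue(s) in %d bout(s), %.0f s stimulation>\n",
    x$cue_label, length(x$cue_times_s), nrow(x$bouts), x$total_stim_s
  ))
  invisible(x)
}

#' Audit a cue schedule against an offline hypnogram
#'
#' Flags every cue falling inside a 20-s offline epoch not scored as
#' non-REM. Because online staging (30-s epochs) and offline scoring (20-s
#' epochs) are independent, a valid online schedule can still earn flags
#' here; the report quantifies that disagreement.
#'
#' @param schedule A `cue_schedule`.
#' @param h The offline [hypnogram()].
#' @return Tibble with one row per cue: `cue_time_s`, `offline_epoch`,
#'   `offline_stage`, `flagged`; attributes `n_flagged` and `total_stim_s`.
#' @export
validate_schedule <- function(schedule, h) {
  h <- as_hypnogram(h)
  es <- epoch_s(h)
  times <- schedule$cue_times_s
  ep <- pmin(floor(times / es), nrow(h) - 1)
  stage <- h$stage[ep + 1]
  out <- tibble(
    cue_time_s = times,
    offline_epoch = as.integer(ep),
    offline_stage = stage,
    flagged = stage != "NREM"
  )
  structure(out,
    n_flagged = sum(out$flagged), total_stim_s = schedule$total_stim_s,
    class = c("cue_audit", class(out))
  )
}

#' Read a cue log CSV (`cue_time_s`, `cue_label`)
#' @param path Path to the CSV.
#' @return Tibble with `cue_time_s`, `cue_label`.
#' @export
read_cue_log <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    cue_time_s = readr::col_double(), cue_label = readr::col_character()
  ))
}

#' Write a cue schedule as a cue log CSV
#' @param schedule A `cue_schedule` (or tibble with `cue_time_s`, `cue_label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cue_log <- function(schedule, path) {
  df <- if (inherits(schedule, "cue_schedule")) {
    tibble(
      cue_time_s = schedule$cue_times_s,
      cue_label = rep(schedule$cue_label, length(schedule$cue_times_s))
    )
  } else {
    as_tibble(schedule)[c("cue_time_s", "cue_label")]
  }
  readr::write_csv(df, path)
  invisible(path)
}
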