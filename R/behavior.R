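# Behavioral learning statistics: cueing benefit, latency reduction and its
# relative (correct/incorrect) form.

.cue_classes <- c("cued_left", "cued_right", "uncued_left", "uncued_right", "center")

#' Read a behavioral trials CSV
#'
#' Columns: `dog_id`, `phase` (`baseline`/`test`), `trial_index` (1-15),
#' `cue_class` (`cued_left`, `cued_right`, `uncued_left`, `uncued_right`,
#' `center`), `correct` (0/1), `latency_s`.
#'
#' @param path Path to the CSV.
#' @return Tibble of trial records.
#' @export
read_trials <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    dog_id = readr::col_character(),
    phase = readr::col_character(),
    trial_index = readr::col_integer(),
    cue_class = readr::col_character(),
    correct = readr::col_integer(),
    latency_s = readr::col_double()
  ))
  bad <- which(!df$phase %in% c("baseline", "test") |
                 !df$cue_class %in% .cue_classes |
                 !df$correct %in% c(0L, 1L) | df$latency_s <= 0)
  if (length(bad)) abort(sprintf("invalid trial record at row %d", bad[1]))
  df
}

#' Write a behavioral trials CSV
#' @param trials Trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

is_cued <- function(cue_class) cue_class %in% c("cued_left", "cued_right")

#' Cueing benefit
#'
#' Post-sleep accuracy minus baseline accuracy on cued trials (both cued
#' sides pooled): the change in the proportion of correct choices for the
#' cue that was replayed during sleep. Positive values indicate a benefit.
#'
#' @param trials Trial tibble for one dog (columns `phase`, `cue_class`,
#'   `correct`).
#' @return Accuracy difference in `[-1, 1]`, or `NA` if either phase lacks
#'   cued trials.
#' @examples
#' tr <- tibble::tibble(
#'   phase = rep(c("baseline", "test"), each = 5),
#'   cue_class = "cued_left",
#'   correct = c(1, 1, 0, 0, 0, 1, 1, 1, 1, 0)
#' )
#' cueing_benefit(tr) # 4/5 - 2/5 = 0.4
#' @export
cueing_benefit <- function(trials) {
  cued <- trials[is_cued(trials$cue_class), ]
  base <- cued$correct[cued$phase == "baseline"]
  test <- cued$correct[cued$phase == "test"]
  if (length(base) == 0 || length(test) == 0) return(NA_real_)
  mean(test) - mean(base)
}

#' Latency reduction for one correctness class
#'
#' The ratio of mean pre-sleep (baseline) latency to mean post-sleep (test)
#' latency among trials of the given correctness class; values above 1 mean
#' responses got faster after sleep. The ratio of per-class means is used
#' because baseline and test trials are unpaired.
#'
#' @param trials Trial tibble for one dog.
#' @param class_correct `1` for correct trials, `0` for incorrect.
#' @return The pre/post latency ratio, or `NA` if the class is absent in
#'   either phase.
#' @export
latency_reduction <- function(trials, class_correct) {
  sel <- trials$correct == class_correct
  pre <- trials$latency_s[sel & trials$phase == "baseline"]
  post <- trials$latency_s[sel & trials$phase == "test"]
  if (length(pre) == 0 || length(post) == 0) return(NA_real_)
  mean(pre) / mean(post)
}

#' Relative latency reduction
#'
#' Latency reduction for correct trials divided by latency reduction for
#' incorrect trials. Values above 1 mean responses to eventually-correct
#' choices sped up more than responses to incorrect ones — a latency-based
#' signature of learning that is invariant to any global rescaling of
#' latencies. `NA` (with a message) when either class reduction is
#' undefined; such dogs are excluded from downstream correlations.
#'
#' @param trials Trial tibble for one dog.
#' @param quiet Suppress the exclusion message.
#' @return The ratio, or `NA`.
#' @export
relative_latency_reduction <- function(trials, quiet = FALSE) {
  rc <- latency_reduction(trials, 1L)
  ri <- latency_reduction(trials, 0L)
  if (is.na(rc) || is.na(ri)) {
    if (!quiet) {
      rlang::inform("relative latency reduction undefined (a correctness class is absent in one phase); dog excluded")
    }
    return(NA_real_)
  }
  rc / ri
}

#' Per-dog behavioral summary
#'
#' Applies [cueing_benefit()], [latency_reduction()] and
#' [relative_latency_reduction()] to every dog in a trial table.
#'
#' @param trials Trial tibble with a `dog_id` column.
#' @return Tibble with one row per dog: `dog_id`, `cueing_benefit`,
#'   `lat_reduction_correct`, `lat_reduction_incorrect`,
#'   `relative_latency_reduction`.
#' @export
behavior_summary <- function(trials) {
  trials %>%
    group_by(.data$dog_id) %>%
    summarise(
      cueing_benefit = cueing_benefit(dplyr::pick(dplyr::everything())),
      lat_reduction_correct = latency_reduction(dplyr::pick(dplyr::everything()), 1L),
      lat_reduction_incorrect = latency_reduction(dplyr::pick(dplyr::everything()), 0L),
      relative_latency_reduction = relative_latency_reduction(
        dplyr::pick(dplyr::everything()), quiet = TRUE
      ),
      .groups = "drop"
    )
}
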