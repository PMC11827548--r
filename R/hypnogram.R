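# Hypnogram container: ordered sleep-stage labels on fixed-length epochs.

#' Sleep stage labels
#'
#' The four stages scored in canine polysomnography. Drowsiness is a genuine
#' transitional stage in carnivores, scored separately from both wake and
#' non-REM sleep.
#'
#' @format Character vector of the canonical stage labels, in wake-to-REM
#'   order: `"WAKE"`, `"DROWSINESS"`, `"NREM"`, `"REM"`.
#' @export
STAGES <- c("WAKE", "DROWSINESS", "NREM", "REM")

# single-letter file codes <-> canonical labels
.stage_codes <- c(WAKE = "W", DROWSINESS = "D", NREM = "N", REM = "R")

stage_from_code <- function(code) {
  out <- names(.stage_codes)[match(code, .stage_codes)]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort(sprintf("unknown stage symbol '%s' at row %d", code[bad], bad))
  }
  out
}

#' Construct a hypnogram
#'
#' A hypnogram is a tibble with one row per scoring epoch (default 20 s) and
#' columns `epoch` (0-based index) and `stage` (one of [STAGES]). The epoch
#' length is carried as an attribute and preserved by the package's
#' operations.
#'
#' @param stages Character vector of stage labels. Either canonical labels
#'   (`"WAKE"`, `"DROWSINESS"`, `"NREM"`, `"REM"`) or the one-letter file
#'   codes (`"W"`, `"D"`, `"N"`, `"R"`).
#' @param epoch_s Epoch length in seconds (default 20, the offline scoring
#'   resolution).
#' @param start_offset_s Recording-time offset of epoch 0, in seconds.
#' @return A `hypnogram` tibble with columns `epoch`, `stage`.
#' @examples
#' hypnogram(c("W", "W", "D", "N", "N", "R"))
#' @export
hypnogram <- function(stages, epoch_s = 20, start_offset_s = 0) {
  if (length(stages) == 0) abort("hypnogram must contain at least one epoch")
  if (!is.numeric(epoch_s) || length(epoch_s) != 1 || epoch_s <= 0) {
    abort("epoch_s must be a single positive number")
  }
  stages <- as.character(stages)
  is_code <- stages %in% .stage_codes
  stages[is_code] <- names(.stage_codes)[match(stages[is_code], .stage_codes)]
  if (!all(stages %in% STAGES)) {
    bad <- which(!(stages %in% STAGES))[1]
    abort(sprintf("unknown stage symbol '%s' at row %d", stages[bad], bad))
  }
  out <- tibble(epoch = seq_along(stages) - 1L, stage = stages)
  structure(out,
    epoch_s = epoch_s, start_offset_s = start_offset_s,
    class = c("hypnogram", class(out))
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf(
    "<hypnogram: %d epochs x %g s = %.1f min>\n",
    nrow(x), epoch_s(x), nrow(x) * epoch_s(x) / 60
  ))
  NextMethod()
}

#' Epoch length of a hypnogram
#'
#' @param h A hypnogram (or any data frame carrying an `epoch_s` attribute).
#' @return Epoch length in seconds; defaults to 20 when the attribute is
#'   absent.
#' @export
epoch_s <- function(h) {
  e <- attr(h, "epoch_s")
  if (is.null(e)) 20 else e
}

as_hypnogram <- function(h, epoch_s = NULL) {
  if (inherits(h, "hypnogram") && is.null(epoch_s)) return(h)
  if (is.character(h) || is.factor(h)) {
    return(hypnogram(as.character(h), epoch_s %||% 20))
  }
  if (is.data.frame(h)) {
    if (!"stage" %in% names(h)) abort("hypnogram data frame needs a 'stage' column")
    return(hypnogram(h$stage, epoch_s %||% attr(h, "epoch_s") %||% 20))
  }
  abort("cannot interpret input as a hypnogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a hypnogram CSV
#'
#' The file format is one row per epoch with columns `epoch_index` (0-based,
#' contiguous) and `stage` in the one-letter code (`W`/`D`/`N`/`R`).
#'
#' @param path Path to the CSV file.
#' @param epoch_s Epoch length in seconds (default 20).
#' @return A [hypnogram()] tibble.
#' @export
read_hypnogram <- function(path, epoch_s = 20) {
  df <- readr::read_csv(path, col_types = readr::cols(
    epoch_index = readr::col_integer(), stage = readr::col_character()
  ))
  if (nrow(df) == 0) abort(sprintf("'%s': no epochs", path))
  if (anyNA(df$epoch_index) || anyNA(df$stage)) {
    abort(sprintf("'%s': missing values at row %d", path,
                  which(!complete.cases(df))[1]))
  }
  if (!identical(df$epoch_index, seq_len(nrow(df)) - 1L)) {
    bad <- which(df$epoch_index != seq_len(nrow(df)) - 1L)[1]
    abort(sprintf("'%s': non-contiguous epoch index at row %d", path, bad))
  }
  hypnogram(df$stage, epoch_s = epoch_s)
}

#' Write a hypnogram CSV
#'
#' @param h A hypnogram.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  h <- as_hypnogram(h)
  readr::write_csv(
    tibble(epoch_index = h$epoch, stage = unname(.stage_codes[h$stage])),
    path
  )
  invisible(path)
}

#' Minutes spent in one stage
#'
#' Optionally excludes artifact-flagged time, for use as a density
#' denominator (events per artifact-free minute).
#'
#' @param h A hypnogram.
#' @param stage One of [STAGES].
#' @param artifacts Optional artifact table (`start_s`, `end_s` half-open
#'   intervals) whose flagged time is excluded. Intervals must lie within the
#'   recording.
#' @param epoch_s Epoch length override in seconds.
#' @return Minutes of the stage (artifact-free minutes when `artifacts` is
#'   given).
#' @examples
#' stage_minutes(hypnogram(c("N", "N", "N")), "NREM")
#' @export
stage_minutes <- function(h, stage, artifacts = NULL, epoch_s = NULL) {
  h <- as_hypnogram(h, epoch_s)
  stopifnot(stage %in% STAGES)
  es <- epoch_s(h)
  idx <- which(h$stage == stage)
  if (length(idx) == 0) return(0)
  total_s <- length(idx) * es
  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    dur_s <- nrow(h) * es
    if (any(artifacts$start_s < 0) || any(artifacts$end_s > dur_s + 1e-9)) {
      abort("artifact intervals extend beyond the recording")
    }
    arts <- normalize_artifacts(artifacts)
    # overlap of each flagged interval with each epoch of the stage
    ep_start <- (idx - 1) * es
    ep_end <- ep_start + es
    cut_s <- 0
    for (k in seq_len(nrow(arts))) {
      ov <- pmin(ep_end, arts$end_s[k]) - pmax(ep_start, arts$start_s[k])
      cut_s <- cut_s + sum(pmax(ov, 0))
    }
    total_s <- total_s - cut_s
  }
  total_s / 60
}
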