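# Artifact interval handling. Manual artifact rejection is scored on 4-s
# subepochs; masks are therefore snapped to a 4-s grid anchored at recording
# start before any spectral or spindle computation.

#' Normalize an artifact interval table
#'
#' Sorts half-open `[start_s, end_s)` intervals and merges overlaps and
#' abutments, so downstream code can assume disjoint ordered intervals.
#'
#' @param artifacts Data frame with `start_s`, `end_s` columns (seconds).
#'   `NULL` or zero rows mean an artifact-free recording.
#' @return Tibble with disjoint, ordered `start_s` / `end_s` columns.
#' @export
normalize_artifacts <- function(artifacts) {
  if (is.null(artifacts) || nrow(artifacts) == 0) {
    return(tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  if (any(artifacts$end_s <= artifacts$start_s)) {
    abort("artifact intervals must satisfy start_s < end_s")
  }
  a <- dplyr::arrange(as_tibble(artifacts[c("start_s", "end_s")]), .data$start_s)
  starts <- a$start_s[1]
  ends <- a$end_s[1]
  for (i in seq_len(nrow(a))[-1]) {
    k <- length(starts)
    if (a$start_s[i] <= ends[k]) {
      ends[k] <- max(ends[k], a$end_s[i])
    } else {
      starts <- c(starts, a$start_s[i])
      ends <- c(ends, a$end_s[i])
    }
  }
  tibble(start_s = starts, end_s = ends)
}

#' Snap artifact intervals to the 4-s rejection grid
#'
#' Expands each interval to the full 4-s subepochs it touches, mirroring
#' manual rejection granularity, then merges the result.
#'
#' @param artifacts Artifact table (`start_s`, `end_s`).
#' @param subepoch_s Grid length in seconds (default 4).
#' @return Normalized tibble of grid-aligned intervals.
#' @export
snap_artifacts <- function(artifacts, subepoch_s = 4) {
  a <- normalize_artifacts(artifacts)
  if (nrow(a) == 0) return(a)
  a$start_s <- floor(a$start_s / subepoch_s) * subepoch_s
  a$end_s <- ceiling(a$end_s / subepoch_s) * subepoch_s
  normalize_artifacts(a)
}

# logical mask over n samples at rate fs: TRUE = artifact-flagged
artifact_sample_mask <- function(artifacts, n, fs) {
  mask <- logical(n)
  a <- normalize_artifacts(artifacts)
  for (i in seq_len(nrow(a))) {
    lo <- max(1L, floor(a$start_s[i] * fs) + 1L)
    hi <- min(n, ceiling(a$end_s[i] * fs))
    if (hi >= lo) mask[lo:hi] <- TRUE
  }
  mask
}

# TRUE where [t0, t1) intersects any artifact interval
intersects_artifact <- function(t0, t1, artifacts) {
  a <- normalize_artifacts(artifacts)
  if (nrow(a) == 0) return(rep(FALSE, length(t0)))
  out <- logical(length(t0))
  for (i in seq_len(nrow(a))) {
    out <- out | (t0 < a$end_s[i] & t1 > a$start_s[i])
  }
  out
}

#' Read an artifact interval CSV
#'
#' @param path CSV with columns `start_s`, `end_s` (half-open, seconds).
#' @return Normalized artifact tibble.
#' @export
read_artifacts <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    start_s = readr::col_double(), end_s = readr::col_double()
  ))
  normalize_artifacts(df)
}

#' Write an artifact interval CSV
#'
#' @param artifacts Artifact table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_artifacts <- function(artifacts, path) {
  readr::write_csv(normalize_artifacts(artifacts), path)
  invisible(path)
}
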