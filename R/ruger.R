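# Bin-by-bin correlation scan over the spectral grid, with Rüger-area
# multiple-comparison correction.

#' Bin-by-bin correlation scan
#'
#' Pearson correlation between a per-subject outcome (e.g. accuracy on cued
#' trials, cueing benefit, relative latency reduction) and relative spectral
#' power at every frequency bin; two-sided p-values from the t transform
#' with n - 2 degrees of freedom. Subjects missing either value are excluded
#' bin-wise and the per-bin n is recorded.
#'
#' @param spectra Subjects-by-bins table: one row per subject, one column
#'   per frequency bin (any columns beyond `subject_id` are treated as
#'   bins), or a plain numeric matrix.
#' @param outcome Numeric vector of per-subject outcomes, aligned with the
#'   rows of `spectra`.
#' @param freqs Bin frequencies; defaults to [spectral_bins()] when the
#'   column count matches, else column indices.
#' @return A `pvalue_grid` tibble: `freq_hz`, `r`, `p`, `n`. Bins with
#'   zero variance (or n < 4) get `NA` r and p.
#' @export
binwise_scan <- function(spectra, outcome, freqs = NULL) {
  m <- spectra
  if (is.data.frame(m)) {
    m <- as.matrix(m[!(names(m) %in% c("subject_id", "dog_id"))])
  }
  storage.mode(m) <- "double"
  if (nrow(m) != length(outcome)) {
    abort("outcome must have one value per spectra row")
  }
  if (is.null(freqs)) {
    freqs <- if (ncol(m) == length(spectral_bins())) spectral_bins() else seq_len(ncol(m))
  }
  if (sum(is.finite(outcome)) < 4) {
    abort("at least 4 subjects with outcome values are required")
  }

  r <- p <- rep(NA_real_, ncol(m))
  n <- integer(ncol(m))
  ok_out <- is.finite(outcome)
  for (j in seq_len(ncol(m))) {
    ok <- ok_out & is.finite(m[, j])
    n[j] <- sum(ok)
    if (n[j] < 4) next
    x <- m[ok, j]
    y <- outcome[ok]
    if (sd(x) == 0 || sd(y) == 0) next
    rj <- stats::cor(x, y)
    r[j] <- rj
    tj <- rj * sqrt((n[j] - 2) / max(1 - rj^2, .Machine$double.eps))
    p[j] <- 2 * pt(abs(tj), df = n[j] - 2, lower.tail = FALSE)
  }
  out <- tibble(freq_hz = freqs, r = r, p = p, n = n)
  structure(out, class = c("pvalue_grid", class(out)))
}

#' @importFrom stats pt
NULL

#' Rüger areas
#'
#' Partitions the conventionally significant bins (p < `alpha`) of an
#' ordered p-value grid into maximal runs of contiguous bins — the Rüger
#' areas — and accepts or rejects each area as a whole: an area is
#' significant iff at least half of its member p-values are below `alpha/2`
#' and at least one third are below `alpha/3` (fractions compared exactly,
#' thresholds strict).
#'
#' @param grid A `pvalue_grid` from [binwise_scan()], or any tibble with
#'   `freq_hz` and `p` ordered by frequency.
#' @param alpha Conventional significance level (default 0.05).
#' @return Tibble with one row per area: `start_freq`, `end_freq`,
#'   `n_bins`, `n_below_half_alpha`, `n_below_third_alpha`, `significant`,
#'   and a list-column `p_values`. Zero rows when no bin is significant.
#' @examples
#' g <- tibble::tibble(freq_hz = 1:5, p = c(0.2, 0.01, 0.01, 0.04, 0.2))
#' ruger_areas(g) # one 3-bin area, significant
#' @export
ruger_areas <- function(grid, alpha = 0.05) {
  if (is.unsorted(grid$freq_hz)) abort("grid must be ordered by frequency")
  sig <- !is.na(grid$p) & grid$p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- purrr::map(keep, function(k) {
    i <- starts[k]:ends[k]
    ps <- grid$p[i]
    nb <- length(ps)
    n_half <- sum(ps < alpha / 2)
    n_third <- sum(ps < alpha / 3)
    tibble(
      start_freq = grid$freq_hz[starts[k]],
      end_freq = grid$freq_hz[ends[k]],
      n_bins = nb,
      n_below_half_alpha = n_half,
      n_below_third_alpha = n_third,
      significant = (n_half >= nb / 2) && (n_third >= nb / 3),
      p_values = list(ps)
    )
  })
  if (length(out) == 0) {
    return(tibble(
      start_freq = numeric(0), end_freq = numeric(0), n_bins = integer(0),
      n_below_half_alpha = integer(0), n_below_third_alpha = integer(0),
      significant = logical(0), p_values = list()
    ))
  }
  bind_rows(out)
}

#' Annotate a p-value grid with its significant Rüger areas
#'
#' @param grid A `pvalue_grid`.
#' @param alpha Conventional significance level.
#' @return The grid with an added logical `in_significant_area` column.
#' @export
flag_significant_bins <- function(grid, alpha = 0.05) {
  areas <- ruger_areas(grid, alpha)
  flag <- rep(FALSE, nrow(grid))
  sig <- areas[areas$significant, ]
  for (i in seq_len(nrow(sig))) {
    flag <- flag | (grid$freq_hz >= sig$start_freq[i] &
                      grid$freq_hz <= sig$end_freq[i])
  }
  grid$in_significant_area <- flag
  grid
}
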