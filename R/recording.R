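# Multi-channel EEG container and channel derivations.

#' Construct an EEG recording
#'
#' Holds a channels-by-time sample matrix in microvolts together with the
#' sampling rate and channel labels. The canine montage used throughout this
#' package is Fz, Cz, F7, F8 referenced to G2.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param channel_labels Character vector naming the rows of `samples`.
#' @param reference Free-text note on the recording reference.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(samples, sample_rate_hz,
                          channel_labels = rownames(samples),
                          reference = "G2") {
  samples <- as.matrix(samples)
  if (is.null(channel_labels)) abort("channel labels are required")
  if (length(channel_labels) != nrow(samples)) {
    abort("one label per channel row is required")
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    abort("sample_rate_hz must be positive")
  }
  rownames(samples) <- channel_labels
  structure(
    list(
      samples = samples,
      sample_rate_hz = sample_rate_hz,
      channel_labels = channel_labels,
      reference = reference
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording: %d channel(s) [%s], %d samples @ %g Hz = %.1f min, ref %s>\n",
    nrow(x$samples), paste(x$channel_labels, collapse = ", "),
    ncol(x$samples), x$sample_rate_hz,
    ncol(x$samples) / x$sample_rate_hz / 60, x$reference
  ))
  invisible(x)
}

#' Bipolar channel derivation
#'
#' Returns the pointwise difference of two referential channels, e.g.
#' `"Fz-Cz"` for the fronto-central derivation used for spectral analysis.
#'
#' @param rec An [eeg_recording()].
#' @param spec Derivation string `"A-B"`, or a single channel name.
#' @return Numeric vector, the derived single-channel signal in microvolts.
#' @examples
#' rec <- eeg_recording(rbind(Fz = c(1, 2), Cz = c(0.5, 1)), 256)
#' derive_channel(rec, "Fz-Cz")
#' @export
derive_channel <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"))
  parts <- strsplit(spec, "-", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  for (p in parts) {
    if (!p %in% rec$channel_labels) {
      abort(sprintf("channel '%s' not present in recording", p))
    }
  }
  if (length(parts) == 1) {
    return(as.numeric(rec$samples[parts, ]))
  }
  if (length(parts) != 2) abort("derivation must be 'A-B' or a channel name")
  as.numeric(rec$samples[parts[1], ] - rec$samples[parts[2], ])
}

# ---- float32 + JSON-header signal files ------------------------------------

#' Write a recording as float32 binary plus JSON header
#'
#' The signal file holds the sample matrix in channel-major order as
#' little-endian float32; the JSON sidecar records channel labels, sampling
#' rate, sample count and reference.
#'
#' @param rec An [eeg_recording()].
#' @param stem Output path without extension; writes `<stem>.f32` and
#'   `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  header <- list(
    channels = rec$channel_labels,
    sample_rate_hz = rec$sample_rate_hz,
    n_samples = ncol(rec$samples),
    reference = rec$reference,
    dtype = "float32-le"
  )
  jsonlite::write_json(header, paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  con <- file(paste0(stem, ".f32"), "wb")
  on.exit(close(con))
  # channel-major: one channel's full trace, then the next
  writeBin(as.numeric(t(rec$samples)), con, size = 4, endian = "little")
  invisible(stem)
}

#' Read a recording written by [write_recording()]
#'
#' @param stem Path stem (without `.f32`/`.json` extension).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(stem) {
  header <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n_ch <- length(header$channels)
  n <- header$n_samples
  con <- file(paste0(stem, ".f32"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n_ch * n, size = 4, endian = "little")
  samples <- t(matrix(x, nrow = n, ncol = n_ch))
  eeg_recording(samples, header$sample_rate_hz,
    channel_labels = header$channels, reference = header$reference
  )
}

# round-trip a numeric vector through float32 so in-memory values equal what
# a float32 file stores
float32_quantize <- function(x) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  r <- rawConnectionValue(con)
  close(con)
  readBin(r, what = "numeric", n = length(x), size = 4, endian = "little")
}
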