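#' Construct an audio signal
#'
#' The elementary carrier of all prosody operations: a mono waveform with its
#' sampling rate. Samples are dimensionless amplitudes in \[-1, 1\].
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate_hz Sampling rate in Hz (default 48000, the stimulus standard).
#' @return An object of class `audio_signal` with elements `samples` and
#'   `rate_hz`.
#' @export
audio_signal <- function(samples, rate_hz = 48000) {
  stopifnot_scalar(rate_hz, "rate_hz", positive = TRUE)
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("samples must be finite", call. = FALSE)
  structure(list(samples = samples, rate_hz = rate_hz),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$rate_hz, duration(x),
              max(abs(x$samples))))
  invisible(x)
}

#' Signal duration in seconds
#' @param x An `audio_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$rate_hz
}

#' Root-mean-square amplitude
#' @param x An `audio_signal` or numeric vector.
#' @return The RMS value.
#' @export
rms <- function(x) {
  v <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  sqrt(mean(v^2))
}

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for mono 16-bit PCM or 32-bit IEEE-float files,
#' the two encodings this package writes.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = readBin(con, "integer", 1, size = 2, endian = "little"),
        channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        rate     = readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "raw", sz - 8))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: ", path, call. = FALSE)
  if (fmt$channels != 1) stop("only mono WAV supported", call. = FALSE)
  samples <- switch(as.character(fmt$format),
    "1" = readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                  signed = TRUE, endian = "little") / 32767,
    "3" = readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                  endian = "little"),
    stop("unsupported WAV encoding ", fmt$format, call. = FALSE))
  audio_signal(samples, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param x An [audio_signal()].
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 16) {
  stopifnot(inherits(x, "audio_signal"), bits %in% c(16, 32))
  n <- length(x$samples)
  bytes <- bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(x$rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(x$rate_hz * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmax(-1, pmin(1, x$samples)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(x$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}
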