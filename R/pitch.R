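#' Track fundamental frequency by frame-wise autocorrelation
#'
#' Short-time autocorrelation tracker: 40 ms frames with a 10 ms hop,
#' search range 75-400 Hz by default (covering the stimulus corpus range).
#' A frame is voiced when its normalised autocorrelation peak exceeds
#' `voicing_threshold` and its level is above a silence floor relative to the
#' utterance peak RMS. The peak lag is refined by parabolic interpolation.
#'
#' @param signal An [audio_signal()].
#' @param frame_s Analysis frame length, seconds.
#' @param hop_s Hop between frame centres, seconds.
#' @param fmin_hz,fmax_hz Search range in Hz (must satisfy
#'   `fmin_hz < fmax_hz < rate/2`).
#' @param voicing_threshold Normalised autocorrelation needed to call a frame
#'   voiced.
#' @param silence_floor_db Frames more than this many dB below the utterance
#'   peak frame RMS are unvoiced.
#' @return A data.frame with columns `time` (frame centre, s), `f0` (Hz, `NA`
#'   on unvoiced frames) and `voiced` (logical).
#' @export
track_f0 <- function(signal, frame_s = 0.04, hop_s = 0.01,
                     fmin_hz = 75, fmax_hz = 400,
                     voicing_threshold = 0.5, silence_floor_db = -40) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  fs <- signal$rate_hz
  if (length(x) == 0) stop("empty signal", call. = FALSE)
  if (!(fmin_hz < fmax_hz && fmax_hz < fs / 2))
    stop("need fmin_hz < fmax_hz < Nyquist", call. = FALSE)
  n <- max(16L, round(frame_s * fs))
  hop <- max(1L, round(hop_s * fs))
  starts <- seq(1L, max(1L, length(x) - n + 1L), by = hop)
  lag_min <- max(2L, floor(fs / fmax_hz))
  lag_max <- min(n - 2L, ceiling(fs / fmin_hz))
  nfft <- 2^ceiling(log2(2L * n))

  frame_rms <- vapply(starts, function(s) {
    fr <- x[s:(s + min(n, length(x) - s + 1L) - 1L)]
    sqrt(mean(fr^2))
  }, numeric(1))
  peak_rms <- max(frame_rms, 1e-12)

  f0 <- rep(NA_real_, length(starts))
  voiced <- rep(FALSE, length(starts))
  for (i in seq_along(starts)) {
    if (20 * log10(frame_rms[i] / peak_rms + 1e-300) < silence_floor_db) next
    s <- starts[i]
    fr <- x[s:(s + min(n, length(x) - s + 1L) - 1L)]
    if (length(fr) < lag_max + 2L) next
    fr <- fr - mean(fr)
    sp <- stats::fft(c(fr, numeric(nfft - length(fr))))
    ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[seq_len(lag_max + 2L)]
    if (ac[1] <= 0) next
    ac <- ac / ac[1]
    idx <- lag_min:lag_max
    j <- idx[which.max(ac[idx + 1L])]
    if (ac[j + 1L] < voicing_threshold) next
    # parabolic refinement around the peak lag
    y0 <- ac[j]; y1 <- ac[j + 1L]; y2 <- ac[j + 2L]
    denom <- y0 - 2 * y1 + y2
    delta <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    f0[i] <- fs / (j + delta)
    voiced[i] <- TRUE
  }
  data.frame(time = (starts - 1L + n / 2) / fs, f0 = f0, voiced = voiced)
}
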