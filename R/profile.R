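#' Acoustic norms of the four emotion prosodies
#'
#' Per-emotion acoustic feature statistics used to calibrate the synthetic
#' stimulus bank: mean and SD of F0 (Hz), mean intensity (dB relative to the
#' bank's maximum RMS), and mean syllable rate (syllables/s), for angry,
#' happy, sad and unemotional prosody, plus the grand means over all speech
#' used as the attenuation targets.
#'
#' @format A data.frame with one row per emotion and columns `emotion`,
#'   `f0_mean_hz`, `f0_sd_hz`, `intensity_db`, `intensity_sd_db`,
#'   `rate_syl_per_s`, `rate_sd_syl_per_s`.
#' @export
emotion_norms <- data.frame(
  emotion = c("angry", "happy", "sad", "unemotional"),
  f0_mean_hz = c(241.47, 243.31, 215.97, 167.04),
  f0_sd_hz = c(6.14, 10.29, 11.44, 8.37),
  intensity_db = c(-0.99, -10.97, -17.76, -15.04),
  intensity_sd_db = c(1.01, 0.85, 1.44, 0.58),
  rate_syl_per_s = c(4.50, 5.57, 4.70, 4.68),
  rate_sd_syl_per_s = c(0.07, 0.18, 0.31, 0.26),
  stringsAsFactors = FALSE
)

#' Attenuation targets for prosody manipulation
#'
#' Grand-mean values over the stimulus corpus: the constant F0 to which F0
#' variation is flattened (217 Hz, the rounded grand mean of 216.95 Hz), the
#' constant short-time level for intensity flattening (-11.19 dB relative to
#' the bank's maximum RMS), and the uniform syllable rate (4.82 syllables/s).
#'
#' @param f0_target_hz Constant F0 target, Hz.
#' @param intensity_target_db Level target, dB re bank max RMS.
#' @param rate_target_syl_per_s Syllable-rate target.
#' @return An object of class `manipulation_targets`.
#' @export
manipulation_targets <- function(f0_target_hz = 217,
                                 intensity_target_db = -11.19,
                                 rate_target_syl_per_s = 4.82) {
  stopifnot_scalar(f0_target_hz, "f0_target_hz", positive = TRUE)
  stopifnot_scalar(intensity_target_db, "intensity_target_db")
  stopifnot_scalar(rate_target_syl_per_s, "rate_target_syl_per_s", positive = TRUE)
  structure(list(f0_target_hz = f0_target_hz,
                 intensity_target_db = intensity_target_db,
                 rate_target_syl_per_s = rate_target_syl_per_s),
            class = "manipulation_targets")
}

#' Measure the prosodic profile of an utterance
#'
#' Computes the statistics used to characterise each stimulus: mean, SD and
#' range of F0 over voiced frames; overall intensity in dB relative to a
#' reference RMS; and syllable rate as syllable count over total duration.
#'
#' @param signal An [audio_signal()].
#' @param n_syllables Known syllable count of the utterance.
#' @param ref_rms Reference RMS defining 0 dB (e.g. the bank maximum).
#' @param ... Passed to [track_f0()].
#' @return An object of class `prosody_profile`: a list with `f0_mean_hz`,
#'   `f0_sd_hz`, `f0_range_hz` (length-2), `intensity_db`, `rate_syl_per_s`,
#'   `prop_voiced`. F0 fields are `NA` for a fully unvoiced signal.
#' @export
measure_profile <- function(signal, n_syllables, ref_rms = 1, ...) {
  stopifnot(inherits(signal, "audio_signal"))
  stopifnot_scalar(ref_rms, "ref_rms", positive = TRUE)
  trk <- track_f0(signal, ...)
  v <- trk$f0[trk$voiced]
  structure(list(
    f0_mean_hz = if (length(v)) mean(v) else NA_real_,
    f0_sd_hz = if (length(v) > 1) stats::sd(v) else NA_real_,
    f0_range_hz = if (length(v)) range(v) else c(NA_real_, NA_real_),
    intensity_db = 20 * log10(rms(signal) / ref_rms),
    rate_syl_per_s = n_syllables / duration(signal),
    prop_voiced = mean(trk$voiced)
  ), class = "prosody_profile")
}

#' Short-time frame levels of an utterance
#'
#' Half-overlapping frame RMS levels in dB relative to `ref_rms`. A frame is
#' flagged speech-active when it lies fully inside speech, i.e. every sample
#' in the frame has a short-time envelope above the silence floor; frames
#' straddling a speech/silence boundary are not active. This is the
#' measurement the frame-wise intensity equalisation targets.
#'
#' @param signal An [audio_signal()].
#' @param ref_rms Reference RMS defining 0 dB.
#' @param frame_s Frame length, seconds.
#' @param silence_floor_db Envelope level (dB re `ref_rms`) separating
#'   speech from silence.
#' @return Data.frame with `time`, `level_db`, `active`.
#' @export
frame_levels <- function(signal, ref_rms, frame_s = 0.05,
                         silence_floor_db = -40) {
  x <- signal$samples
  fs <- signal$rate_hz
  n <- max(16L, round(frame_s * fs))
  env <- st_envelope(x, fs, frame_s)
  above <- env > ref_rms * 10^(silence_floor_db / 20)
  # erode by a frame length: the envelope estimate has frame-length support,
  # so levels within it of a speech/silence boundary are biased
  half <- n
  cs <- cumsum(c(0, !above))
  interior <- vapply(seq_along(x), function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    cs[hi + 1L] - cs[lo] == 0
  }, logical(1))
  starts <- seq(1L, max(1L, length(x) - n + 1L), by = n %/% 2L)
  lv <- vapply(starts, function(s)
    20 * log10(sqrt(mean(x[s:(s + n - 1L)]^2)) / ref_rms + 1e-300),
    numeric(1))
  act <- vapply(starts, function(s) all(interior[s:(s + n - 1L)]), logical(1))
  data.frame(time = (starts - 1L + n / 2) / fs, level_db = lv, active = act)
}

#' @export
print.prosody_profile <- function(x, ...) {
  cat(sprintf(
    "<prosody_profile> F0 %.1f Hz (SD %.1f, range %.1f-%.1f), %.2f dB, %.2f syl/s\n",
    x$f0_mean_hz, x$f0_sd_hz, x$f0_range_hz[1], x$f0_range_hz[2],
    x$intensity_db, x$rate_syl_per_s))
  invisible(x)
}
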