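#' Specification of a synthetic pseudo-sentence
#'
#' Describes a six-syllable-style utterance as a sequence of voiced harmonic
#' syllables separated by silent gaps. The synthetic sentences are acoustic
#' surrogates for recorded pseudo-sentences: they carry the three prosodic
#' features under study (F0 contour, per-syllable intensity, syllable rate)
#' without any segmental content.
#'
#' @param n_syllables Number of syllables (>= 1; the study design uses 6).
#' @param syllable_durations Seconds per syllable (recycled to `n_syllables`).
#' @param gap_durations Seconds of silence between syllables (recycled to
#'   `n_syllables - 1`).
#' @param f0_contour Either a single frequency in Hz, or a function of time
#'   (seconds, relative to utterance onset) returning Hz over voiced spans.
#'   Must stay within \[50, 500\] Hz.
#' @param syllable_gains Linear amplitude per syllable (recycled).
#' @param seed Integer seed recorded with the spec (synthesis itself is
#'   deterministic; the seed identifies the spec within a generated bank).
#' @return An object of class `sentence_spec`.
#' @export
sentence_spec <- function(n_syllables = 6,
                          syllable_durations = 0.18,
                          gap_durations = 0.06,
                          f0_contour = 220,
                          syllable_gains = 0.3,
                          seed = 1L) {
  stopifnot(n_syllables >= 1)
  syllable_durations <- rep_len(syllable_durations, n_syllables)
  gap_durations <- if (n_syllables > 1) rep_len(gap_durations, n_syllables - 1) else numeric(0)
  syllable_gains <- rep_len(syllable_gains, n_syllables)
  if (any(syllable_durations <= 0) || any(gap_durations < 0))
    stop("durations must be positive (gaps non-negative)", call. = FALSE)
  structure(list(n_syllables = as.integer(n_syllables),
                 syllable_durations = syllable_durations,
                 gap_durations = gap_durations,
                 f0_contour = f0_contour,
                 syllable_gains = syllable_gains,
                 seed = as.integer(seed)),
            class = "sentence_spec")
}

contour_fun <- function(f0_contour) {
  if (is.function(f0_contour)) return(f0_contour)
  stopifnot_scalar(f0_contour, "f0_contour", positive = TRUE)
  function(t) rep_len(f0_contour, length(t))
}

#' Synthesize a pseudo-sentence waveform
#'
#' Each syllable is a harmonic complex (8 harmonics, -6 dB/octave roll-off)
#' following the spec's F0 contour by phase accumulation, shaped by a raised
#' cosine onset/offset ramp, and scaled by its syllable gain. Syllables are
#' separated by silent gaps. Synthesis is deterministic: the same spec always
#' yields a bit-identical waveform.
#'
#' @param spec A [sentence_spec()].
#' @param rate_hz Sampling rate in Hz.
#' @param n_harmonics Number of harmonics in the voiced source.
#' @param ramp_s Raised-cosine onset/offset ramp per syllable, seconds.
#' @return An [audio_signal()].
#' @export
synth_sentence <- function(spec, rate_hz = 48000, n_harmonics = 8,
                           ramp_s = 0.015) {
  stopifnot(inherits(spec, "sentence_spec"))
  f0 <- contour_fun(spec$f0_contour)
  total <- sum(spec$syllable_durations) + sum(spec$gap_durations)
  probe <- f0(seq(0, total, length.out = 257))
  if (any(probe < 50 | probe > 500))
    stop("f0_contour outside [50, 500] Hz", call. = FALSE)

  out <- numeric(round(total * rate_hz))
  t0 <- 0
  for (k in seq_len(spec$n_syllables)) {
    dur <- spec$syllable_durations[k]
    i0 <- round(t0 * rate_hz)
    n <- round(dur * rate_hz)
    tt <- t0 + (seq_len(n) - 1) / rate_hz
    inst_f0 <- f0(tt)
    phase <- 2 * pi * cumsum(inst_f0) / rate_hz
    x <- numeric(n)
    for (h in seq_len(n_harmonics)) {
      # skip harmonics above Nyquist
      if (max(inst_f0) * h >= rate_hz / 2) break
      x <- x + sin(h * phase) / h
    }
    nr <- max(2L, round(ramp_s * rate_hz))
    env <- rep(1, n)
    up <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
    env[seq_len(nr)] <- up
    env[n - nr + seq_len(nr)] <- rev(up)
    x <- x * env
    x <- x / sqrt(mean(x^2)) * spec$syllable_gains[k]
    out[i0 + seq_len(n)] <- x
    t0 <- t0 + dur + if (k < spec$n_syllables) spec$gap_durations[k] else 0
  }
  peak <- max(abs(out))
  if (peak > 1) out <- out / peak * 0.99
  audio_signal(out, rate_hz)
}

#' Draw a random sentence spec
#'
#' Used by the property suite and the bank generator: durations, gains and a
#' smoothly varying F0 contour around a target mean are drawn from seeded
#' distributions.
#'
#' @param seed Integer seed.
#' @param f0_mean_hz Target time-average F0 over voiced spans.
#' @param f0_excursion Relative depth of the sinusoidal contour modulation
#'   (0 = monotone).
#' @param rate_syl_per_s Target syllable rate (syllables per second of total
#'   utterance duration).
#' @param gain Overall linear amplitude scale.
#' @param n_syllables Number of syllables.
#' @return A [sentence_spec()].
#' @export
random_sentence_spec <- function(seed, f0_mean_hz = 220, f0_excursion = 0.12,
                                 rate_syl_per_s = 4.86, gain = 0.3,
                                 n_syllables = 6) {
  with_seed(seed, {
    total <- n_syllables / rate_syl_per_s
    gap_frac <- runif(1, 0.2, 0.3)
    syl <- runif(n_syllables, 0.8, 1.2)
    syl <- syl / sum(syl) * total * (1 - gap_frac)
    gaps <- if (n_syllables > 1) {
      g <- runif(n_syllables - 1, 0.8, 1.2)
      g / sum(g) * total * gap_frac
    } else numeric(0)
    cycles <- sample(2:4, 1)
    phi <- runif(1, 0, 2 * pi)
    depth <- min(f0_excursion, 0.9 * min(f0_mean_hz - 55, 495 - f0_mean_hz) / f0_mean_hz)
    modulation <- local({
      d <- depth; cy <- cycles; tt_total <- total; p0 <- phi
      function(t) 1 + d * sin(2 * pi * cy * t / tt_total + p0)
    })
    # normalise so the mean over voiced analysis frames is the target: use
    # the tracker's frame grid (40 ms frames, 10 ms hop), counting frames
    # whose window lies mostly within a syllable, as the measurement does
    centres <- seq(0.02, total - 0.02, by = 0.01)
    voiced_t <- centres[vapply(centres, function(tc) {
      lo <- tc - 0.02; hi <- tc + 0.02
      ov <- 0
      for (k in seq_len(n_syllables)) {
        on <- sum(syl[seq_len(k - 1)]) + sum(gaps[seq_len(k - 1)])
        ov <- ov + max(0, min(hi, on + syl[k]) - max(lo, on))
      }
      ov >= 0.5 * (hi - lo)
    }, logical(1))]
    mbar <- mean(modulation(voiced_t))
    contour <- local({
      fm <- f0_mean_hz; m <- modulation; mb <- mbar
      function(t) fm * m(t) / mb
    })
    gains <- gain * runif(n_syllables, 0.7, 1.3)
    sentence_spec(n_syllables = n_syllables, syllable_durations = syl,
                  gap_durations = gaps, f0_contour = contour,
                  syllable_gains = gains, seed = seed)
  })
}
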