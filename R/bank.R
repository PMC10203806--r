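#' Generate a calibrated synthetic stimulus bank
#'
#' Synthesizes `n_sentences_per_emotion` pseudo-sentences per emotion whose
#' per-emotion prosody statistics are calibrated to supplied norms (F0
#' mean/SD, relative level, syllable rate), then derives every requested
#' manipulated condition from each natural sentence. Per-sentence deviations
#' from the emotion means are drawn from the norm SDs and re-centred so each
#' emotion's realised mean matches its norm; sentence levels are expressed
#' relative to the bank's maximum RMS, which defines 0 dB.
#'
#' @param norms Data.frame like [emotion_norms] (one row per emotion with
#'   `f0_mean_hz`, `f0_sd_hz`, `intensity_db`, `rate_syl_per_s`).
#' @param n_sentences_per_emotion Sentences per emotion.
#' @param conditions Character vector of condition names to realise (always
#'   includes the underlying natural recordings).
#' @param seed Integer seed; the same seed yields a bit-identical bank.
#' @param targets [manipulation_targets()] used for the manipulated versions.
#' @param rate_hz Sampling rate.
#' @param n_syllables Syllables per sentence.
#' @return An object of class `stimulus_bank`: list with `signals` (named
#'   list of [audio_signal()]), `meta` (data.frame: id, emotion, condition,
#'   sentence, f0_mean_hz, intensity_db, rate_syl_per_s measured on the
#'   natural versions), `ref_rms` (bank maximum RMS), `targets`.
#' @export
make_stimulus_bank <- function(norms = emotion_norms,
                               n_sentences_per_emotion = 5,
                               conditions = condition_names(),
                               seed = 1L,
                               targets = manipulation_targets(),
                               rate_hz = 48000,
                               n_syllables = 6) {
  stopifnot(all(c("emotion", "f0_mean_hz", "f0_sd_hz", "intensity_db",
                  "intensity_sd_db", "rate_syl_per_s", "rate_sd_syl_per_s")
                %in% names(norms)))
  if (any(norms$f0_mean_hz < 85 | norms$f0_mean_hz > 380))
    stop("per-emotion F0 mean outside feasible synthesis range", call. = FALSE)
  conditions <- match.arg(conditions, condition_names(), several.ok = TRUE)

  centred <- function(n, sd) {
    if (n == 1) return(0)
    z <- stats::rnorm(n, 0, sd)
    z - mean(z)
  }

  draws <- with_seed(substream_seed(seed, "bank"), {
    do.call(rbind, lapply(seq_len(nrow(norms)), function(e) {
      n <- n_sentences_per_emotion
      data.frame(
        emotion = norms$emotion[e],
        sentence = seq_len(n),
        f0 = norms$f0_mean_hz[e] + centred(n, norms$f0_sd_hz[e]),
        level_db = norms$intensity_db[e] + centred(n, norms$intensity_sd_db[e]),
        rate = pmax(2, norms$rate_syl_per_s[e] +
                      centred(n, norms$rate_sd_syl_per_s[e])),
        spec_seed = vapply(seq_len(n), function(i)
          substream_seed(seed, paste0(norms$emotion[e], i)), integer(1)),
        stringsAsFactors = FALSE)
    }))
  })
  if (any(draws$f0 < 85 | draws$f0 > 380))
    stop("drawn sentence F0 outside feasible synthesis range", call. = FALSE)

  naturals <- lapply(seq_len(nrow(draws)), function(i) {
    sp <- random_sentence_spec(draws$spec_seed[i], f0_mean_hz = draws$f0[i],
                               rate_syl_per_s = draws$rate[i], gain = 1,
                               n_syllables = n_syllables)
    synth_sentence(sp, rate_hz = rate_hz)
  })

  # scale so levels sit at the drawn dB re the bank max RMS, peak-safe
  rel_db <- draws$level_db - max(draws$level_db)
  crest <- vapply(naturals, function(s) max(abs(s$samples)) / rms(s), numeric(1))
  ref_rms <- 0.9 / max(crest * 10^(rel_db / 20))
  naturals <- lapply(seq_along(naturals), function(i) {
    s <- naturals[[i]]
    audio_signal(s$samples / rms(s) * ref_rms * 10^(rel_db[i] / 20), rate_hz)
  })

  signals <- list()
  meta <- NULL
  for (i in seq_len(nrow(draws))) {
    prof <- measure_profile(naturals[[i]], n_syllables, ref_rms)
    for (cn in conditions) {
      id <- sprintf("%s_s%d_%s", draws$emotion[i], draws$sentence[i],
                    gsub("\\+", "-", cn))
      signals[[id]] <- if (cn == "natural") naturals[[i]] else
        apply_condition(naturals[[i]], cn, targets, bank_ref_rms = ref_rms,
                        n_syllables = n_syllables)
      meta <- rbind(meta, data.frame(
        id = id, emotion = draws$emotion[i], condition = cn,
        sentence = draws$sentence[i],
        f0_mean_hz = prof$f0_mean_hz, intensity_db = prof$intensity_db,
        rate_syl_per_s = prof$rate_syl_per_s, stringsAsFactors = FALSE))
    }
  }
  structure(list(signals = signals, meta = meta, ref_rms = ref_rms,
                 targets = targets, seed = seed),
            class = "stimulus_bank")
}

#' @export
print.stimulus_bank <- function(x, ...) {
  cat(sprintf("<stimulus_bank> %d signals (%d emotions x %d sentences), ref RMS %.4g\n",
              length(x$signals), length(unique(x$meta$emotion)),
              max(x$meta$sentence), x$ref_rms))
  invisible(x)
}

#' Concatenate sentences into a stimulation block
#'
#' Concatenates sentences with silent gaps, optionally overlaying a pure tone
#' (the attention-trial probe) at a given onset.
#'
#' @param sentences List of [audio_signal()] with a common sampling rate.
#' @param gap_s Silent gap between successive sentences, seconds.
#' @param tone Optional list `(freq_hz, dur_s, onset_s, amp)` describing an
#'   additive tone; it must fit inside the block.
#' @return An [audio_signal()] of duration `sum(durations) + gaps`.
#' @export
concat_block <- function(sentences, gap_s = 0, tone = NULL) {
  stopifnot(length(sentences) >= 1)
  fs <- sentences[[1]]$rate_hz
  if (!all(vapply(sentences, function(s) s$rate_hz == fs, logical(1))))
    stop("sentences must share a sampling rate", call. = FALSE)
  gap <- numeric(round(gap_s * fs))
  parts <- list()
  for (i in seq_along(sentences)) {
    parts[[length(parts) + 1L]] <- sentences[[i]]$samples
    if (i < length(sentences)) parts[[length(parts) + 1L]] <- gap
  }
  x <- unlist(parts)
  if (!is.null(tone)) {
    amp <- if (is.null(tone$amp)) 0.1 else tone$amp
    i0 <- round(tone$onset_s * fs)
    n <- round(tone$dur_s * fs)
    if (i0 < 0 || i0 + n > length(x))
      stop("tone extends past block end", call. = FALSE)
    x[i0 + seq_len(n)] <- x[i0 + seq_len(n)] +
      amp * sin(2 * pi * tone$freq_hz * (seq_len(n) - 1) / fs)
  }
  audio_signal(pmax(-1, pmin(1, x)), fs)
}
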