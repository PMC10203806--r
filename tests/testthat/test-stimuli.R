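test_that("synthesis is deterministic, linear in gains, and tracks its contour", {
  sp <- sentence_spec(f0_contour = 220, syllable_gains = 0.15)
  s1 <- synth_sentence(sp)
  s2 <- synth_sentence(sp)
  expect_identical(s1$samples, s2$samples)

  trk <- track_f0(s1)
  expect_lt(abs(mean(trk$f0[trk$voiced]) - 220), 2)

  # doubling gains doubles RMS (linearity, below the clipping guard)
  sp2 <- sp
  sp2$syllable_gains <- sp$syllable_gains * 2
  expect_equal(rms(synth_sentence(sp2)), 2 * rms(s1), tolerance = 1e-6)

  expect_error(synth_sentence(sentence_spec(f0_contour = 30)), "50")
})

test_that("tracker flags white noise unvoiced and follows a glide", {
  set.seed(42)
  noise <- audio_signal(stats::rnorm(48000) * 0.1, 48000)
  trk <- track_f0(noise)
  expect_gte(mean(!trk$voiced), 0.9)

  expect_error(track_f0(audio_signal(numeric(0))), "empty")
  expect_error(track_f0(noise, fmin_hz = 300, fmax_hz = 200), "Nyquist")

  glide <- synth_sentence(sentence_spec(
    f0_contour = function(t) 150 + 100 * t,
    syllable_durations = 0.2, gap_durations = 0.05))
  trk <- track_f0(glide)
  tv <- trk[trk$voiced, ]
  expected <- 150 + 100 * tv$time
  expect_lt(stats::median(abs(tv$f0 - expected)), 5)
})

test_that("measure_profile reports the defining arithmetic", {
  s <- synth_sentence(sentence_spec(f0_contour = 200,
                                    syllable_durations = 0.15,
                                    gap_durations = 0.06))
  # 6 syllables, duration 6*0.15 + 5*0.06 = 1.2 s -> 5 syl/s
  prof <- measure_profile(s, n_syllables = 6, ref_rms = rms(s))
  expect_equal(prof$rate_syl_per_s, 5, tolerance = 1e-6)
  expect_equal(prof$intensity_db, 0, tolerance = 1e-9)
  expect_lt(abs(prof$f0_mean_hz - 200), 2)
})

test_that("F0 flattening hits the target, preserves duration, and is near-identity on flat input", {
  glide <- synth_sentence(sentence_spec(
    f0_contour = function(t) 150 + 100 * t,
    syllable_durations = 0.2, gap_durations = 0.05))
  flat <- attenuate_f0(glide, 217)
  trk <- track_f0(flat)
  expect_lt(abs(mean(trk$f0[trk$voiced]) - 217), 3)
  expect_lt(stats::sd(trk$f0[trk$voiced]), 3)
  ratio <- duration(flat) / duration(glide)
  expect_true(ratio >= 0.99 && ratio <= 1.01)

  already <- synth_sentence(sentence_spec(f0_contour = 217))
  again <- attenuate_f0(already, 217)
  expect_lt(log_spectral_distance(already, again), 6)

  expect_error(attenuate_f0(glide, 30), "range")
})

test_that("intensity equalisation levels active frames and shifts with the reference", {
  sp <- sentence_spec(f0_contour = 210,
                      syllable_gains = c(1, 0.5, 0.8, 0.3, 0.6, 0.9) * 0.3)
  s <- synth_sentence(sp)
  ref <- rms(s) * 2
  out <- attenuate_intensity(s, -11.19, ref)
  fl <- frame_levels(out, ref)
  expect_lt(abs(mean(fl$level_db[fl$active]) + 11.19), 0.2)
  expect_lt(max(abs(fl$level_db[fl$active] + 11.19)), 1)

  # doubling the reference shifts the achieved level by +6.02 dB re the old one
  out2 <- attenuate_intensity(s, -11.19, ref * 2)
  fl2 <- frame_levels(out2, ref)
  expect_equal(mean(fl2$level_db[fl2$active]) - mean(fl$level_db[fl$active]),
               20 * log10(2), tolerance = 0.1)

  expect_warning(attenuate_intensity(audio_signal(numeric(100)), -11, 1),
                 "silent")
})

test_that("time-scale modification sets the exact duration and preserves pitch", {
  sp <- random_sentence_spec(5, f0_mean_hz = 250, rate_syl_per_s = 4.0,
                             f0_excursion = 0.2)
  s <- synth_sentence(sp)
  out <- attenuate_rate(s, 4.82, 6)
  expect_equal(duration(out), 6 / 4.82, tolerance = 0.01)

  t0 <- track_f0(s); t1 <- track_f0(out)
  expect_lt(abs(mean(t0$f0[t0$voiced]) - mean(t1$f0[t1$voiced])), 3)

  # input already at target: duration change below 1%
  at_target <- synth_sentence(random_sentence_spec(6, rate_syl_per_s = 4.82))
  out2 <- attenuate_rate(at_target, 4.82, 6)
  expect_lt(abs(duration(out2) / duration(at_target) - 1), 0.01)

  expect_error(attenuate_rate(s, 50, 6), "outside")
})

test_that("condition composition applies the right feature subset", {
  expect_error(condition("bogus"), "unknown")
  expect_identical(condition("natural")$attenuated, character(0))

  sp <- random_sentence_spec(7, f0_mean_hz = 250, rate_syl_per_s = 4.2,
                             f0_excursion = 0.15)
  s <- synth_sentence(sp)
  tg <- manipulation_targets()

  expect_identical(apply_condition(s, "natural", tg)$samples, s$samples)

  out <- apply_condition(s, "rate+F0", tg, bank_ref_rms = rms(s), n_syllables = 6)
  trk <- track_f0(out)
  expect_lt(abs(mean(trk$f0[trk$voiced]) - 217), 3)
  expect_equal(duration(out), 6 / 4.82, tolerance = 0.01)

  out2 <- apply_condition(s, "intensity+F0", tg, bank_ref_rms = rms(s) * 2,
                          n_syllables = 6)
  t2 <- track_f0(out2)
  fl <- frame_levels(out2, rms(s) * 2)
  expect_lt(abs(mean(t2$f0[t2$voiced]) - 217), 3)
  expect_lt(abs(mean(fl$level_db[fl$active]) + 11.19), 0.3)
  expect_equal(duration(out2), duration(s))
})

test_that("attenuations are idempotent within tolerance", {
  s <- synth_sentence(random_sentence_spec(9, f0_mean_hz = 260,
                                           f0_excursion = 0.15))
  f1 <- attenuate_f0(s, 217)
  f2 <- attenuate_f0(f1, 217)
  t1 <- track_f0(f1); t2 <- track_f0(f2)
  expect_lt(abs(mean(t1$f0[t1$voiced]) - mean(t2$f0[t2$voiced])), 2)

  ref <- rms(s)
  i1 <- attenuate_intensity(s, -11.19, ref)
  i2 <- attenuate_intensity(i1, -11.19, ref)
  l1 <- frame_levels(i1, ref); l2 <- frame_levels(i2, ref)
  expect_lt(abs(mean(l1$level_db[l1$active]) - mean(l2$level_db[l2$active])), 0.1)

  r1 <- attenuate_rate(s, 4.82, 6)
  r2 <- attenuate_rate(r1, 4.82, 6)
  expect_equal(duration(r1), duration(r2), tolerance = 1e-6)
})

test_that("profile measurement recovers spec parameters across seeded specs", {
  for (seed in 1:10) {
    f0 <- 150 + 15 * seed
    rate <- 4 + 0.15 * seed
    sp <- random_sentence_spec(seed, f0_mean_hz = f0, rate_syl_per_s = rate,
                               gain = 0.2)
    s <- synth_sentence(sp)
    prof <- measure_profile(s, 6, ref_rms = 1)
    expect_lt(abs(prof$f0_mean_hz - f0), 2)
    expect_lt(abs(prof$rate_syl_per_s / rate - 1), 0.02)
    expect_true(all(abs(s$samples) <= 1))
  }
})

test_that("stimulus bank is seeded, calibrated and within amplitude bounds", {
  b1 <- make_stimulus_bank(conditions = "natural", seed = 7,
                           n_sentences_per_emotion = 3)
  b2 <- make_stimulus_bank(conditions = "natural", seed = 7,
                           n_sentences_per_emotion = 3)
  expect_identical(b1$signals[[1]]$samples, b2$signals[[1]]$samples)

  nat <- b1$meta[b1$meta$condition == "natural", ]
  per_emotion <- tapply(nat$f0_mean_hz, nat$emotion, mean)
  for (e in names(per_emotion)) {
    target <- emotion_norms$f0_mean_hz[emotion_norms$emotion == e]
    expect_lt(abs(per_emotion[[e]] - target), 3)
  }
  expect_true(all(vapply(b1$signals, function(s) max(abs(s$samples)) <= 1,
                         logical(1))))

  bad <- emotion_norms
  bad$f0_mean_hz[1] <- 600
  expect_error(make_stimulus_bank(norms = bad), "range")
})

test_that("manipulated bank members satisfy their per-feature oracles", {
  bank <- make_stimulus_bank(conditions = c("natural", "rate+F0"),
                             n_sentences_per_emotion = 2, seed = 11)
  manip <- bank$meta[bank$meta$condition == "rate+F0", ]
  for (id in manip$id) {
    s <- bank$signals[[id]]
    trk <- track_f0(s)
    expect_lt(abs(mean(trk$f0[trk$voiced]) - 217), 3)
    expect_equal(duration(s), 6 / 4.82, tolerance = 0.01)
  }
})

test_that("block concatenation adds gaps and the attention tone", {
  s <- synth_sentence(sentence_spec(syllable_durations = 0.15,
                                    gap_durations = 0.05))
  five <- replicate(5, s, simplify = FALSE)
  blk <- concat_block(five, gap_s = 0.2)
  expect_equal(duration(blk), 5 * duration(s) + 4 * 0.2, tolerance = 1e-6)

  expect_identical(concat_block(list(s), gap_s = 0)$samples, s$samples)

  tone_blk <- concat_block(five, gap_s = 0.2,
                           tone = list(freq_hz = 400, dur_s = 0.5,
                                       onset_s = 1.0, amp = 0.2))
  fs <- tone_blk$rate_hz
  span <- tone_blk$samples[round(1.05 * fs):round(1.45 * fs)]
  pre <- blk$samples[round(1.05 * fs):round(1.45 * fs)]
  pwr <- function(x, f) {
    n <- length(x)
    abs(sum(x * exp(-2i * pi * f * (seq_len(n) - 1) / fs)))^2 / n
  }
  expect_gt(pwr(span, 400), pwr(pre, 400) + 10)

  expect_error(concat_block(five, 0.2, tone = list(freq_hz = 400, dur_s = 1,
                                                   onset_s = duration(blk) - 0.1)),
               "past")
})

test_that("WAV files round-trip", {
  s <- synth_sentence(sentence_spec())
  tf <- tempfile(fileext = ".wav")
  write_wav(s, tf)
  back <- read_wav(tf)
  expect_equal(back$rate_hz, 48000)
  expect_lt(max(abs(back$samples - s$samples)), 1e-4)
  write_wav(s, tf, bits = 32)
  expect_lt(max(abs(read_wav(tf)$samples - s$samples)), 1e-6)
  unlink(tf)
})
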