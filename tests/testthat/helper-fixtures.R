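# Shared fixtures, built in code at test time.

# compact montage: one long + one short channel per ROI
tiny_montage <- function() {
  make_montage(stats::setNames(rep(1L, 6), roi_names()),
               stats::setNames(rep(1L, 6), roi_names()))
}

# short block schedule without familiarisation/attention trials
tiny_schedule <- function(reps = 8, seed = 1L,
                          conditions = c("angry", "happy", "sad",
                                         "unemotional", "control")) {
  make_block_schedule(experimental_conditions = conditions, reps = reps,
                      attention_stimuli = character(0), attention_reps = 0,
                      n_familiarization = 0, seed = seed)
}

schedule_events <- function(sched) {
  tr <- sched$trials
  data.frame(onset = tr$onset_s, duration = tr$duration_s,
             trial_type = tr$condition, kind = tr$kind,
             stringsAsFactors = FALSE)
}

# true ROI amplitude per (condition, roi, chromophore) row of an estimate table
true_amplitude <- function(est, truth) {
  ratio <- ifelse(est$chromophore == "HbO", 1, truth$hbr_ratio)
  ratio * truth$beta[cbind(est$condition, est$roi)]
}

# mean log-spectral distance (dB) between two equal-length signals over
# frames, a phase-insensitive similarity measure
log_spectral_distance <- function(a, b, nfft = 4096) {
  stopifnot(length(a$samples) == length(b$samples))
  n <- min(length(a$samples), nfft)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  spec <- function(x) {
    s <- abs(stats::fft(x[seq_len(n)] * w))[seq_len(n / 2)]
    20 * log10(s + 1e-8)
  }
  keep <- spec(a$samples) > -20   # compare where there is signal energy
  mean(abs(spec(a$samples) - spec(b$samples))[keep])
}
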