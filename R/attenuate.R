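#' Experimental condition: which prosodic features are attenuated
#'
#' The five stimulus conditions are named for the attenuated features:
#' `natural` (none), `intensity+rate`, `F0`, `intensity+F0`, `rate+F0`.
#'
#' @param name Condition name, one of the five above.
#' @return An object of class `emo_condition` with fields `name` and
#'   `attenuated` (character subset of `c("F0", "intensity", "rate")`).
#' @export
condition <- function(name) {
  subsets <- list(
    "natural" = character(0),
    "intensity+rate" = c("intensity", "rate"),
    "F0" = "F0",
    "intensity+F0" = c("intensity", "F0"),
    "rate+F0" = c("rate", "F0"))
  if (!name %in% names(subsets))
    stop("unknown condition: ", name, call. = FALSE)
  structure(list(name = name, attenuated = subsets[[name]]),
            class = "emo_condition")
}

#' All five stimulus conditions
#' @return Character vector of the five condition names.
#' @export
condition_names <- function() {
  c("natural", "intensity+rate", "F0", "intensity+F0", "rate+F0")
}

# Voiced sample segments from an F0 track: runs of voiced frames (bridging
# single-frame dropouts), mapped to sample index ranges.
voiced_segments <- function(trk, fs, n_samples) {
  v <- trk$voiced
  # bridge isolated unvoiced frames inside voiced runs
  if (length(v) > 2) {
    inner <- which(!v[-c(1, length(v))]) + 1L
    bridge <- inner[v[inner - 1L] & v[inner + 1L]]
    v[bridge] <- TRUE
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < 3) next
    t0 <- trk$time[starts[i]]
    t1 <- trk$time[ends[i]]
    s0 <- max(1L, floor((t0 - 0.02) * fs) + 1L)
    s1 <- min(n_samples, ceiling((t1 + 0.02) * fs))
    segs[[length(segs) + 1L]] <- c(s0, s1)
  }
  segs
}

# Short-time RMS envelope: centred moving average of x^2 over `frame_s`.
st_envelope <- function(x, fs, frame_s = 0.05) {
  n <- max(16L, round(frame_s * fs))
  pad <- c(rep(0, n), x^2, rep(0, n))
  ma <- as.numeric(stats::filter(pad, rep(1 / n, n), sides = 2))
  sqrt(pmax(ma[n + seq_along(x)], 0))
}

# Samples at least one frame length inside a speech region (envelope above
# the floor); the envelope estimate is biased within a frame of a boundary.
speech_interior <- function(above, n) {
  cs <- cumsum(c(0, !above))
  N <- length(above)
  lo <- pmax(1L, seq_len(N) - n)
  hi <- pmin(N, seq_len(N) + n)
  cs[hi + 1L] - cs[lo] == 0
}

# Linear interpolation of the F0 contour over a voiced segment (samples).
interp_f0 <- function(trk, fs, s0, s1) {
  vt <- trk$time[trk$voiced]
  vf <- trk$f0[trk$voiced]
  tt <- (s0:s1 - 1L) / fs
  stats::approx(vt, vf, xout = tt, rule = 2)$y
}

#' Flatten F0 variation to a constant target
#'
#' Pitch-synchronous overlap-add (TD-PSOLA) resynthesis: pitch marks are laid
#' down along the tracked F0 contour, two-period Hann-windowed grains are
#' extracted at the analysis marks, and the grains are re-placed at the
#' constant target period. Unvoiced and silent spans are untouched and the
#' duration is preserved exactly.
#'
#' @param signal An [audio_signal()] containing voiced spans.
#' @param target_hz Constant F0 target (must lie inside the tracker range).
#' @param fmin_hz,fmax_hz Tracker search range passed to [track_f0()].
#' @return An [audio_signal()] of identical length whose voiced frames track
#'   at `target_hz`.
#' @export
attenuate_f0 <- function(signal, target_hz, fmin_hz = 75, fmax_hz = 400) {
  stopifnot(inherits(signal, "audio_signal"))
  if (target_hz < fmin_hz || target_hz > fmax_hz)
    stop("target_hz outside tracker range", call. = FALSE)
  x <- signal$samples
  fs <- signal$rate_hz
  trk <- track_f0(signal, fmin_hz = fmin_hz, fmax_hz = fmax_hz)
  if (!any(trk$voiced)) stop("no voiced spans found", call. = FALSE)
  segs <- voiced_segments(trk, fs, length(x))
  out <- x
  p_syn <- fs / target_hz
  for (seg in segs) {
    s0 <- seg[1]; s1 <- seg[2]
    f0s <- interp_f0(trk, fs, s0, s1)
    nseg <- s1 - s0 + 1L
    # analysis pitch marks by phase accumulation along the local period
    amarks <- numeric(0)
    pos <- 1 + fs / f0s[1] / 2
    while (pos <= nseg) {
      amarks <- c(amarks, pos)
      pos <- pos + fs / f0s[min(nseg, max(1L, round(pos)))]
    }
    if (length(amarks) < 2) next
    smarks <- seq(amarks[1], nseg, by = p_syn)
    acc <- numeric(nseg)
    wsum <- numeric(nseg)
    for (sm in smarks) {
      am <- amarks[which.min(abs(amarks - sm))]
      la <- round(fs / f0s[max(1L, min(nseg, round(am)))])  # one local period
      lo_a <- round(am) - la; hi_a <- round(am) + la
      grain_idx <- lo_a:hi_a
      w <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(grain_idx))))
      src <- s0 - 1L + grain_idx
      valid <- src >= 1L & src <= length(x)
      g <- numeric(length(grain_idx))
      g[valid] <- x[src[valid]]
      dst <- round(sm) + (grain_idx - round(am))
      keep <- dst >= 1L & dst <= nseg
      acc[dst[keep]] <- acc[dst[keep]] + g[keep] * w[keep]
      wsum[dst[keep]] <- wsum[dst[keep]] + w[keep]
    }
    nz <- wsum > 1e-6
    acc[nz] <- acc[nz] / wsum[nz]
    acc[!nz] <- x[s0 - 1L + which(!nz)]
    # short crossfades into the untouched surround
    nf <- min(32L, nseg %/% 4L)
    if (nf > 1) {
      fade <- seq(0, 1, length.out = nf)
      acc[1:nf] <- fade * acc[1:nf] + (1 - fade) * x[s0 - 1L + 1:nf]
      acc[(nseg - nf + 1):nseg] <- rev(fade) * acc[(nseg - nf + 1):nseg] +
        fade * x[s0 - 1L + (nseg - nf + 1):nseg]
    }
    out[s0:s1] <- acc
  }
  peak <- max(abs(out))
  if (peak > 1) {
    message("rescaling to avoid clipping (peak ", round(peak, 3), ")")
    out <- out / peak * 0.99
  }
  audio_signal(out, fs)
}

#' Equalise short-time intensity to a constant level
#'
#' Frame-wise gain normalisation: the short-time RMS of every speech-active
#' frame is driven to `ref_rms * 10^(target_db/20)`; frames below the silence
#' floor keep unit gain. Gains are linearly interpolated between frame
#' centres so the applied gain contour is smooth.
#'
#' @param signal An [audio_signal()].
#' @param target_db Target level in dB relative to `ref_rms`.
#' @param ref_rms Reference RMS defining 0 dB (e.g. the bank maximum RMS).
#' @param frame_s Frame length, seconds.
#' @param silence_floor_db Frames below this level (dB re `ref_rms`) are left
#'   untouched.
#' @param global If `TRUE`, apply a single utterance-wide gain instead of the
#'   frame-wise contour (levels the overall RMS only).
#' @return An [audio_signal()] of identical length.
#' @export
attenuate_intensity <- function(signal, target_db, ref_rms,
                                frame_s = 0.05, silence_floor_db = -40,
                                global = FALSE) {
  stopifnot(inherits(signal, "audio_signal"))
  stopifnot_scalar(ref_rms, "ref_rms", positive = TRUE)
  x <- signal$samples
  fs <- signal$rate_hz
  target_rms <- ref_rms * 10^(target_db / 20)
  if (all(abs(x) < 1e-12)) {
    warning("all-silent signal returned unchanged")
    return(signal)
  }
  if (global) {
    out <- x * target_rms / rms(x)
  } else {
    floor_lin <- ref_rms * 10^(silence_floor_db / 20)
    n <- max(16L, round(frame_s * fs))
    out <- x
    # drive the short-time envelope onto the target level inside speech;
    # gains are estimated on the speech interior (where the envelope is
    # unbiased) and extended to onset/offset edges, a second pass corrects
    # residual bias
    for (pass in 1:2) {
      e <- st_envelope(out, fs, frame_s)
      above <- e > floor_lin
      interior <- speech_interior(above, n)
      g <- rep(1, length(x))
      if (any(interior)) {
        gi <- target_rms / e[interior]
        idx <- which(interior)
        g[above] <- stats::approx(idx, gi, xout = which(above), rule = 2)$y
      }
      # short smoothing so the gain contour has no jumps at the floor edge
      ns <- max(3L, round(0.005 * fs))
      g <- as.numeric(stats::filter(c(rep(g[1], ns), g, rep(g[length(g)], ns)),
                                    rep(1 / ns, ns), sides = 2))[ns + seq_along(g)]
      out <- out * g
    }
  }
  peak <- max(abs(out))
  if (peak > 1) {
    message("rescaling to avoid clipping (peak ", round(peak, 3), ")")
    out <- out / peak * 0.99
  }
  audio_signal(out, fs)
}

#' Scale syllable rate by pitch-preserving time-scale modification
#'
#' Uniform, sentence-level WSOLA (waveform-similarity overlap-add): the
#' output duration is set to `n_syllables / target_syl_per_s` and successive
#' Hann-windowed segments are chosen by cross-correlation alignment so that
#' pitch and timbre are preserved while duration changes.
#'
#' @param signal An [audio_signal()].
#' @param target_syl_per_s Target syllable rate.
#' @param n_syllables Syllable count of the utterance.
#' @param win_s Analysis window length, seconds.
#' @param search_s Alignment search half-width, seconds.
#' @return An [audio_signal()] of duration `n_syllables / target_syl_per_s`.
#' @export
attenuate_rate <- function(signal, target_syl_per_s, n_syllables,
                           win_s = 0.04, search_s = 0.010) {
  stopifnot(inherits(signal, "audio_signal"), n_syllables >= 1)
  stopifnot_scalar(target_syl_per_s, "target_syl_per_s", positive = TRUE)
  x <- signal$samples
  fs <- signal$rate_hz
  n_in <- length(x)
  n_out <- round(n_syllables / target_syl_per_s * fs)
  alpha <- n_out / n_in           # stretch factor (output/input)
  if (alpha < 0.25 || alpha > 4)
    stop("time-scale factor ", round(alpha, 3), " outside [0.25, 4]",
         call. = FALSE)
  if (abs(alpha - 1) < 1e-9) return(signal)

  N <- 2L * (round(win_s * fs) %/% 2L)
  Hs <- N %/% 2L
  delta <- round(search_s * fs)
  win <- 0.5 * (1 - cos(2 * pi * (0:(N - 1L)) / N))
  out <- numeric(n_out + N)
  wsum <- numeric(n_out + N)
  xpad <- c(x, numeric(N + delta + 1L))

  prev_start <- 1L
  k <- 0L
  repeat {
    po <- k * Hs + 1L
    if (po > n_out) break
    pi_nom <- round((po - 1L) / alpha) + 1L
    if (k == 0L) {
      sel <- 1L
    } else {
      # natural continuation of the previously selected segment
      ref <- xpad[(prev_start + Hs):(prev_start + Hs + N - 1L)]
      lo <- max(1L, pi_nom - delta)
      hi <- min(length(xpad) - N, pi_nom + delta)
      cand_n <- hi - lo + 1L
      if (cand_n <= 1L) {
        sel <- max(1L, min(pi_nom, length(xpad) - N))
      } else {
        # cross-correlation over the candidate offsets via FFT
        seg <- xpad[lo:(hi + N - 1L)]
        nfft <- 2^ceiling(log2(length(seg)))
        cc <- Re(stats::fft(stats::fft(c(seg, numeric(nfft - length(seg)))) *
                              Conj(stats::fft(c(ref, numeric(nfft - N)))),
                            inverse = TRUE))[seq_len(cand_n)]
        sel <- lo + which.max(cc) - 1L
      }
    }
    seg <- xpad[sel:(sel + N - 1L)] * win
    out[po:(po + N - 1L)] <- out[po:(po + N - 1L)] + seg
    wsum[po:(po + N - 1L)] <- wsum[po:(po + N - 1L)] + win
    prev_start <- sel
    k <- k + 1L
  }
  nz <- wsum > 1e-6
  out[nz] <- out[nz] / wsum[nz]
  audio_signal(out[seq_len(n_out)], fs)
}

#' Apply an experimental condition to an utterance
#'
#' Composes the per-feature attenuations for the condition's feature subset
#' in the fixed order F0, then rate, then intensity. The `natural` condition
#' returns the input unchanged.
#'
#' @param signal An [audio_signal()].
#' @param cond An [condition()] object or condition name.
#' @param targets A [manipulation_targets()] object.
#' @param bank_ref_rms Reference RMS (bank maximum) defining 0 dB for the
#'   intensity stage.
#' @param n_syllables Syllable count (needed for the rate stage).
#' @param order Feature order; the default is the standard composition order.
#' @return The manipulated [audio_signal()].
#' @export
apply_condition <- function(signal, cond, targets = manipulation_targets(),
                            bank_ref_rms = rms(signal), n_syllables = 6,
                            order = c("F0", "rate", "intensity")) {
  if (is.character(cond)) cond <- condition(cond)
  stopifnot(inherits(cond, "emo_condition"),
            inherits(targets, "manipulation_targets"))
  out <- signal
  for (feat in order) {
    if (!feat %in% cond$attenuated) next
    out <- switch(feat,
      "F0" = attenuate_f0(out, targets$f0_target_hz),
      "rate" = attenuate_rate(out, targets$rate_target_syl_per_s, n_syllables),
      "intensity" = attenuate_intensity(out, targets$intensity_target_db,
                                        bank_ref_rms))
  }
  out
}
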