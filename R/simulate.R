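#' Haemoglobin extinction coefficients
#'
#' Base-10 molar extinction coefficients (1/(cm*M)) of oxy- and
#' deoxyhaemoglobin at the two instrument wavelengths, from the standard
#' compiled tabulation of Gratzer & Kollias spectra. The analysis converts
#' them to natural-log units per micromolar and centimetre internally.
#'
#' @param wavelengths Wavelengths in nm (only 760 and 850 are tabulated).
#' @return A 2x2 matrix, rows = wavelengths, columns = c("HbO", "HbR").
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  tab <- matrix(c(586, 1548.52,
                  1058, 691.32),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("760", "850"), c("HbO", "HbR")))
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab)))
    stop("extinction coefficients tabulated only for 760 and 850 nm",
         call. = FALSE)
  tab[key, , drop = FALSE]
}

# natural-log extinction per (µM * cm)
extinction_ln_uM_cm <- function(wavelengths = c(760, 850)) {
  extinction_coefficients(wavelengths) * log(10) * 1e-6
}

#' Simulated ground truth for one participant
#'
#' Per-condition, per-ROI HbO response amplitudes in micromolar; the HbR
#' amplitude is the HbO amplitude times the (negative) `hbr_ratio`.
#'
#' @param beta Numeric matrix, rows = conditions, columns = ROIs, of HbO
#'   amplitudes (µM). Rownames/colnames required.
#' @param hbr_ratio HbR/HbO neural amplitude ratio; must be negative.
#' @return An object of class `nirs_truth`.
#' @export
ground_truth <- function(beta, hbr_ratio = -1 / 3) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  if (!is.finite(hbr_ratio) || hbr_ratio >= 0)
    stop("hbr_ratio must be negative", call. = FALSE)
  structure(list(beta = beta, hbr_ratio = hbr_ratio), class = "nirs_truth")
}

#' Default speech-vs-silence ground truth
#'
#' Speech conditions activate bilateral STG (larger on the right) with
#' smaller frontal responses; the silent control has zero amplitude
#' everywhere.
#'
#' @param conditions Condition labels; `"control"` rows are zero.
#' @param stg_amp HbO amplitude in STG, µM.
#' @param right_bias Multiplier for right-STG relative to left.
#' @param frontal_amp HbO amplitude in IFG/MFG, µM.
#' @param hbr_ratio Passed to [ground_truth()].
#' @return A `nirs_truth`.
#' @export
default_truth <- function(conditions = c("angry", "happy", "sad",
                                         "unemotional", "control"),
                          stg_amp = 1, right_bias = 1.3, frontal_amp = 0.2,
                          hbr_ratio = -1 / 3) {
  beta <- matrix(0, nrow = length(conditions), ncol = 6,
                 dimnames = list(conditions, roi_names()))
  speech <- setdiff(conditions, "control")
  beta[speech, "LSTG"] <- stg_amp
  beta[speech, "RSTG"] <- stg_amp * right_bias
  beta[speech, c("LIFG", "RIFG", "LMFG", "RMFG")] <- frontal_amp
  ground_truth(beta, hbr_ratio)
}

#' Systemic-physiology noise configuration
#'
#' Shared latent oscillations (Mayer-wave ~0.1 Hz, respiratory ~0.25 Hz,
#' cardiac ~1.1 Hz) weighted per channel, a random-walk drift, and white
#' measurement noise. Short channels carry exactly these non-neural
#' components. Amplitudes are micromolar on the HbO scale; HbR systemic
#' components are scaled by `hbr_systemic_scale`.
#'
#' @param mayer_amp,resp_amp,cardiac_amp Component amplitudes (µM).
#' @param mayer_freq_hz,resp_freq_hz,cardiac_freq_hz Component frequencies.
#' @param drift_sd Per-sample SD of the random-walk drift (µM).
#' @param white_sd SD of white noise (µM).
#' @param weight_sd SD of the channel-specific coupling weights around 1.
#' @param hbr_systemic_scale Scale of systemic/drift/white components in HbR.
#' @return An object of class `nirs_noise`.
#' @export
noise_config <- function(mayer_amp = 0.5, resp_amp = 0.2, cardiac_amp = 0.3,
                         mayer_freq_hz = 0.1, resp_freq_hz = 0.25,
                         cardiac_freq_hz = 1.1,
                         drift_sd = 0.01, white_sd = 0.3,
                         weight_sd = 0.3, hbr_systemic_scale = 0.5) {
  cfg <- list(mayer_amp = mayer_amp, resp_amp = resp_amp,
              cardiac_amp = cardiac_amp, mayer_freq_hz = mayer_freq_hz,
              resp_freq_hz = resp_freq_hz, cardiac_freq_hz = cardiac_freq_hz,
              drift_sd = drift_sd, white_sd = white_sd,
              weight_sd = weight_sd, hbr_systemic_scale = hbr_systemic_scale)
  if (any(unlist(cfg[c("mayer_amp", "resp_amp", "cardiac_amp", "drift_sd",
                       "white_sd")]) < 0))
    stop("noise amplitudes must be non-negative", call. = FALSE)
  structure(cfg, class = "nirs_noise")
}

#' Silent noise configuration (all amplitudes zero)
#' @return A `nirs_noise` with every amplitude zero.
#' @export
noise_off <- function() {
  noise_config(mayer_amp = 0, resp_amp = 0, cardiac_amp = 0,
               drift_sd = 0, white_sd = 0, weight_sd = 0)
}

# Exact single-block response: continuous convolution of a `boxcar_s`
# boxcar with the canonical HRF, i.e. H(t) - H(t - boxcar_s) with H the
# cumulative HRF integral, evaluated on a fine grid and peak-normalised so
# a unit-amplitude response peaks at 1. Returns an interpolating function.
block_response_fun <- function(boxcar_s = 3, span_s = 32, dt = 0.01) {
  tt <- seq(0, span_s + boxcar_s, by = dt)
  H <- cumsum(hrf_canonical(tt)) * dt
  Hf <- function(t) {
    t <- pmax(0, pmin(t, max(tt)))
    stats::approx(tt, H, xout = t)$y
  }
  r <- Hf(tt) - Hf(tt - boxcar_s)
  peak <- max(r)
  list(fun = stats::approxfun(tt, r / peak, yleft = 0, yright = 0),
       span = max(tt))
}

# condition regressors: sampled continuous boxcar (x) HRF responses at each
# onset of each condition; free of onset-phase discretisation error at any
# analysis rate
condition_regressors <- function(events, rate_hz, n, boxcar_s = 3,
                                 conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(events$trial_type)
  br <- block_response_fun(boxcar_s)
  tt <- (seq_len(n) - 1) / rate_hz
  X <- matrix(0, nrow = n, ncol = length(conditions),
              dimnames = list(NULL, conditions))
  for (j in seq_along(conditions)) {
    ons <- events$onset[events$trial_type == conditions[j]]
    if (length(ons) && any(ons * rate_hz > n))
      stop("event beyond recording end", call. = FALSE)
    col <- numeric(n)
    for (o in ons) {
      idx <- which(tt >= o & tt <= o + br$span)
      col[idx] <- col[idx] + br$fun(tt[idx] - o)
    }
    X[, j] <- col
  }
  X
}

#' Simulate per-channel haemoglobin concentration time courses
#'
#' Long channels receive the HRF-convolved condition responses of their ROI
#' (scaled by the ground-truth amplitudes) plus systemic oscillations, drift
#' and white noise; short channels receive only the non-neural components.
#'
#' @param montage A [make_montage()] montage.
#' @param events Events data.frame (`onset`, `duration`, `trial_type`); only
#'   rows whose `trial_type` appears in the truth's conditions contribute
#'   event-locked responses.
#' @param truth A [ground_truth()] object.
#' @param noise A [noise_config()] object.
#' @param duration_s Recording length, seconds.
#' @param rate_hz Sampling rate (instrument rate 2.6 Hz).
#' @param seed Integer seed.
#' @param boxcar_s Boxcar length of the response model, seconds.
#' @return List with `hbo`, `hbr` (time x channel matrices, µM), `time`,
#'   `rate_hz`, `montage`, `events`, `truth`.
#' @export
simulate_concentrations <- function(montage, events, truth,
                                    noise = noise_config(),
                                    duration_s = NULL, rate_hz = 2.6,
                                    seed = 1L, boxcar_s = 3) {
  stopifnot(inherits(truth, "nirs_truth"), inherits(noise, "nirs_noise"))
  if (is.null(duration_s))
    duration_s <- max(events$onset + events$duration) + 40
  n <- round(duration_s * rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz
  conditions <- rownames(truth$beta)
  ev <- events[events$trial_type %in% conditions, , drop = FALSE]
  if (nrow(ev) && max(ev$onset) > duration_s)
    stop("events beyond recording span", call. = FALSE)
  R <- condition_regressors(ev, rate_hz, n, boxcar_s, conditions)
  nch <- nrow(montage)

  with_seed(substream_seed(seed, "conc"), {
    lat <- cbind(
      noise$mayer_amp * sin(2 * pi * noise$mayer_freq_hz * tt + stats::runif(1, 0, 2 * pi)),
      noise$resp_amp * sin(2 * pi * noise$resp_freq_hz * tt + stats::runif(1, 0, 2 * pi)),
      noise$cardiac_amp * sin(2 * pi * noise$cardiac_freq_hz * tt + stats::runif(1, 0, 2 * pi)))
    make_chrom <- function(scale) {
      w <- matrix(stats::rnorm(3 * nch, 1, noise$weight_sd), nrow = 3)
      sys <- lat %*% w * scale
      drift <- apply(matrix(stats::rnorm(n * nch, 0, noise$drift_sd * scale), n, nch),
                     2, cumsum)
      white <- matrix(stats::rnorm(n * nch, 0, noise$white_sd * scale), n, nch)
      sys + drift + white
    }
    hbo <- make_chrom(1)
    hbr <- make_chrom(noise$hbr_systemic_scale)
    for (c_i in seq_len(nch)) {
      if (montage$is_short[c_i]) next
      roi <- montage$roi[c_i]
      amp <- truth$beta[, roi]
      neural <- as.numeric(R %*% amp)
      hbo[, c_i] <- hbo[, c_i] + neural
      hbr[, c_i] <- hbr[, c_i] + neural * truth$hbr_ratio
    }
    colnames(hbo) <- colnames(hbr) <- montage$channel
    list(hbo = hbo, hbr = hbr, time = tt, rate_hz = rate_hz,
         montage = montage, events = events, truth = truth)
  })
}

#' Convert concentrations to raw dual-wavelength intensities
#'
#' Inverse of the modified Beer-Lambert law:
#' `I_lambda(t) = I0 * exp(-(eps_HbO * C_HbO(t) + eps_HbR * C_HbR(t)) * d * ppf)`
#' with the channel's source-detector distance `d` and partial pathlength
#' factor `ppf`. Intensities are strictly positive by construction.
#'
#' @param conc Output of [simulate_concentrations()].
#' @param ppf Partial pathlength factor (DPF / partial-volume correction).
#' @param baseline_intensity Baseline intensity `I0` (arbitrary units).
#' @param wavelengths Instrument wavelengths, nm.
#' @return A `nirs_recording`: list with `intensity` (named list of
#'   time x channel matrices per wavelength), `rate_hz`, `montage`,
#'   `events`, `wavelengths`, and the simulation `truth`.
#' @export
concentrations_to_raw <- function(conc, ppf = 0.1, baseline_intensity = 1,
                                  wavelengths = c(760, 850)) {
  if (anyNA(conc$hbo) || anyNA(conc$hbr))
    stop("NaN concentrations", call. = FALSE)
  E <- extinction_ln_uM_cm(wavelengths)
  d_cm <- conc$montage$distance_mm / 10
  intensity <- lapply(seq_along(wavelengths), function(w) {
    od <- sweep(conc$hbo, 2, E[w, "HbO"] * d_cm * ppf, `*`) +
      sweep(conc$hbr, 2, E[w, "HbR"] * d_cm * ppf, `*`)
    baseline_intensity * exp(-od)
  })
  names(intensity) <- as.character(wavelengths)
  structure(list(intensity = intensity, rate_hz = conc$rate_hz,
                 montage = conc$montage, events = conc$events,
                 wavelengths = wavelengths, truth = conc$truth,
                 ppf = ppf),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf(
    "<nirs_recording> %d channels (%d short) x %d samples @ %g Hz, wavelengths %s nm\n",
    nrow(x$montage), sum(x$montage$is_short), nrow(x$intensity[[1]]),
    x$rate_hz, paste(x$wavelengths, collapse = "/")))
  invisible(x)
}

#' Simulate a complete fNIRS recording for one participant
#'
#' Convenience wrapper: block schedule -> concentrations -> raw intensities.
#'
#' @param schedule A `trial_schedule` from [make_block_schedule()] (or an
#'   events data.frame).
#' @inheritParams simulate_concentrations
#' @inheritParams concentrations_to_raw
#' @return A `nirs_recording`.
#' @export
simulate_recording <- function(montage = make_montage(),
                               schedule = make_block_schedule(),
                               truth = default_truth(),
                               noise = noise_config(),
                               seed = 1L, rate_hz = 2.6, ppf = 0.1,
                               baseline_intensity = 1) {
  events <- if (inherits(schedule, "trial_schedule")) {
    tr <- schedule$trials
    data.frame(onset = tr$onset_s, duration = tr$duration_s,
               trial_type = tr$condition, kind = tr$kind,
               stringsAsFactors = FALSE)
  } else schedule
  conc <- simulate_concentrations(montage, events, truth, noise,
                                  rate_hz = rate_hz, seed = seed)
  concentrations_to_raw(conc, ppf = ppf,
                        baseline_intensity = baseline_intensity)
}
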