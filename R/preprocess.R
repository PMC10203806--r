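#' Polyphase rational resampling
#'
#' Classic anti-aliased rate conversion by `p/q`: upsample by zero-stuffing
#' with factor `p`, filter with a windowed-sinc (Hamming) low-pass FIR at
#' the tighter of the two Nyquist bounds with group-delay compensation,
#' then take every `q`-th sample. Edges are padded by reflection so the
#' filter start-up does not distort the series ends.
#'
#' @param x Numeric series.
#' @param p,q Upsampling and downsampling integer factors.
#' @param half_order Filter half-length in multiples of `max(p, q)`.
#' @return The resampled series of length `floor(length(x) * p / q)` (+/- 1).
#' @export
resample_poly <- function(x, p, q, half_order = 10L) {
  p <- as.integer(p); q <- as.integer(q)
  stopifnot(p >= 1, q >= 1)
  n <- length(x)
  m <- max(p, q)
  L <- 2L * half_order * m + 1L              # odd tap count, linear phase
  k <- seq_len(L) - (L + 1L) / 2L
  fc <- 1 / (2 * m)                          # cycles per upsampled sample
  h <- 2 * fc * sinc_fn(2 * fc * k) *
    (0.54 + 0.46 * cos(2 * pi * k / (L - 1L)))
  h <- p * h / sum(h)
  # reflect-pad, zero-stuff, filter via FFT convolution, downsample
  pad <- ceiling((L - 1L) / 2L / p) + 1L
  xp <- c(rev(x[seq_len(min(pad, n))]), x, rev(x[n + 1L - seq_len(min(pad, n))]))
  up <- numeric(length(xp) * p)
  up[seq(1L, length(up), by = p)] <- xp
  nfft <- 2^ceiling(log2(length(up) + L))
  conv <- Re(stats::fft(stats::fft(c(up, numeric(nfft - length(up)))) *
                          stats::fft(c(h, numeric(nfft - L))),
                        inverse = TRUE)) / nfft
  delay <- (L - 1L) / 2L
  start <- delay + pad * p + 1L
  n_out <- floor(n * p / q)
  idx <- start + (seq_len(n_out) - 1L) * q
  conv[idx]
}

sinc_fn <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

#' Resample a recording to a lower rate
#'
#' Anti-aliased polyphase resampling of every channel and wavelength, using
#' the small-integer rational approximation of `target_rate_hz / rate_hz`
#' (2.6 -> 0.6 Hz is the ratio 3/13).
#'
#' @param recording A `nirs_recording`.
#' @param target_rate_hz New sampling rate, must be below the current rate.
#' @return The recording resampled, with `rate_hz` updated.
#' @export
resample_recording <- function(recording, target_rate_hz = 0.6) {
  stopifnot(inherits(recording, "nirs_recording"))
  if (target_rate_hz >= recording$rate_hz)
    stop("target rate must be below the recording rate", call. = FALSE)
  pq <- rational_approx(target_rate_hz / recording$rate_hz, max_den = 100L)
  recording$intensity <- lapply(recording$intensity, function(m) {
    out <- apply(m, 2, resample_poly, p = pq[["p"]], q = pq[["q"]])
    colnames(out) <- colnames(m)
    out
  })
  recording$rate_hz <- recording$rate_hz * pq[["p"]] / pq[["q"]]
  recording
}

#' Convert raw intensities to optical density
#'
#' `OD(t) = -ln(I(t) / mean(I))` per channel and wavelength, using the
#' absolute raw intensities. Scale-invariant: multiplying a channel's
#' intensity by a constant leaves its OD unchanged.
#'
#' @param recording A `nirs_recording`.
#' @return List of time x channel OD matrices, one per wavelength, with the
#'   recording's `rate_hz`, `montage` and `events` attached.
#' @export
to_optical_density <- function(recording) {
  stopifnot(inherits(recording, "nirs_recording"))
  od <- lapply(recording$intensity, function(m) {
    bad <- colnames(m)[apply(m, 2, function(x) any(x <= 0))]
    if (length(bad))
      stop("non-positive intensity in channel(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    -log(sweep(m, 2, colMeans(m), `/`))
  })
  list(od = od, rate_hz = recording$rate_hz, montage = recording$montage,
       events = recording$events, wavelengths = recording$wavelengths)
}

#' Modified Beer-Lambert law: optical density to chromophore concentrations
#'
#' Solves the per-channel 2x2 system `OD = E C d ppf` for the HbO and HbR
#' concentration changes, where `E` is the extinction matrix at the two
#' wavelengths (natural-log units per µM per cm), `d` the source-detector
#' distance and `ppf` the partial pathlength factor (differential pathlength
#' factor over partial volume correction; 6/60 = 0.1 by default). Output is
#' in micromolar.
#'
#' @param od Output of [to_optical_density()].
#' @param ppf Partial pathlength factor.
#' @return List with `hbo` and `hbr` time x channel matrices (µM), plus
#'   `rate_hz`, `montage`, `events`.
#' @export
beer_lambert <- function(od, ppf = 0.1) {
  stopifnot_scalar(ppf, "ppf", positive = TRUE)
  E <- extinction_ln_uM_cm(od$wavelengths)
  if (abs(det(E)) < 1e-12) stop("singular extinction matrix", call. = FALSE)
  Einv <- solve(E)
  d_cm <- od$montage$distance_mm / 10
  od1 <- od$od[[1]]; od2 <- od$od[[2]]
  hbo <- sweep(od1 * Einv["HbO", 1] + od2 * Einv["HbO", 2], 2, d_cm * ppf, `/`)
  hbr <- sweep(od1 * Einv["HbR", 1] + od2 * Einv["HbR", 2], 2, d_cm * ppf, `/`)
  list(hbo = hbo, hbr = hbr, rate_hz = od$rate_hz, montage = od$montage,
       events = od$events)
}

#' Select long channels by source-detector distance
#'
#' Keeps channels whose distance lies inside `[min_mm, max_mm]` (inclusive);
#' short-separation channels are always excluded from GLM targets.
#'
#' @param montage A `nirs_montage`.
#' @param min_mm,max_mm Inclusive distance bounds in mm.
#' @return The montage subset of retained long channels.
#' @export
select_long_channels <- function(montage, min_mm = 20, max_mm = 40) {
  keep <- !montage$is_short & montage$distance_mm >= min_mm &
    montage$distance_mm <= max_mm
  if (!any(keep)) stop("no channels retained", call. = FALSE)
  montage[keep, , drop = FALSE]
}
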