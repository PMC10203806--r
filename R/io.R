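#' Write / read a recording as a plain-text channel-table bundle
#'
#' Serialises a `nirs_recording` as a directory holding one CSV of raw
#' intensities per wavelength (columns = channels), the montage TSV, the
#' events TSV, and a YAML header with sampling rate and wavelengths. The
#' round trip is lossless to numeric-text precision.
#'
#' @param recording A `nirs_recording`.
#' @param path Directory to create/write.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `nirs_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "nirs_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (w in names(recording$intensity)) {
    utils::write.csv(as.data.frame(recording$intensity[[w]]),
                     file.path(path, paste0("intensity_", w, "nm.csv")),
                     row.names = FALSE)
  }
  write_montage(recording$montage, file.path(path, "montage.tsv"))
  write_events(recording$events, file.path(path, "events.tsv"))
  yaml::write_yaml(list(rate_hz = recording$rate_hz,
                        wavelengths = recording$wavelengths,
                        ppf = recording$ppf),
                   file.path(path, "meta.yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.yaml")
  if (!file.exists(meta_path)) stop("missing meta.yaml in ", path, call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  for (f in c("rate_hz", "wavelengths"))
    if (is.null(meta[[f]])) stop("meta.yaml missing field: ", f, call. = FALSE)
  intensity <- lapply(meta$wavelengths, function(w) {
    f <- file.path(path, paste0("intensity_", w, "nm.csv"))
    if (!file.exists(f)) stop("missing wavelength table: ", f, call. = FALSE)
    as.matrix(utils::read.csv(f, check.names = FALSE))
  })
  names(intensity) <- as.character(meta$wavelengths)
  structure(list(intensity = intensity, rate_hz = meta$rate_hz,
                 montage = read_montage(file.path(path, "montage.tsv")),
                 events = read_events(file.path(path, "events.tsv")),
                 wavelengths = meta$wavelengths, truth = NULL,
                 ppf = meta$ppf),
            class = "nirs_recording")
}

#' Run configuration for the end-to-end pipeline
#'
#' All tunable parameters of the simulation/analysis chain with their
#' standard defaults; serialisable to/from YAML. Unknown keys in a config
#' file are an error (silent misconfiguration protection).
#'
#' @param seed Root seed; every stage derives a named substream from it.
#' @param n_participants Simulated participants.
#' @param conditions Experimental condition labels (incl. silent control).
#' @param reps Block repetitions per condition.
#' @param long_per_roi,short_per_roi Montage channel counts per ROI.
#' @param stg_amp,right_bias,frontal_amp,hbr_ratio Ground-truth amplitudes.
#' @param noise A [noise_config()] (or list of its arguments).
#' @param target_rate_hz,boxcar_s,drift_cutoff_hz,ppf First-level settings.
#' @param isi_range_s,block_dur_s Schedule settings.
#' @param weighting ROI pooling weights.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L, n_participants = 22,
                       conditions = c("angry", "happy", "sad",
                                      "unemotional", "control"),
                       reps = 20,
                       long_per_roi = stats::setNames(rep(10L, 6), roi_names()),
                       short_per_roi = stats::setNames(c(2L, 2L, 1L, 1L, 1L, 1L),
                                                       roi_names()),
                       stg_amp = 1, right_bias = 1.3, frontal_amp = 0.2,
                       hbr_ratio = -1 / 3,
                       noise = noise_config(),
                       target_rate_hz = 0.6, boxcar_s = 3,
                       drift_cutoff_hz = 0.01, ppf = 0.1,
                       isi_range_s = c(13, 23), block_dur_s = 7.25,
                       weighting = "inv_se") {
  if (n_participants < 1) stop("need at least 1 participant", call. = FALSE)
  if (is.list(noise) && !inherits(noise, "nirs_noise"))
    noise <- do.call(noise_config, noise)
  cfg <- list(seed = seed, n_participants = n_participants,
              conditions = conditions, reps = reps,
              long_per_roi = long_per_roi, short_per_roi = short_per_roi,
              stg_amp = stg_amp, right_bias = right_bias,
              frontal_amp = frontal_amp, hbr_ratio = hbr_ratio,
              noise = noise, target_rate_hz = target_rate_hz,
              boxcar_s = boxcar_s, drift_cutoff_hz = drift_cutoff_hz,
              ppf = ppf, isi_range_s = isi_range_s,
              block_dur_s = block_dur_s, weighting = weighting)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lst <- unclass(cfg)
  lst$noise <- unclass(lst$noise)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(lst$long_per_roi)) lst$long_per_roi <- unlist(lst$long_per_roi)
  if (!is.null(lst$short_per_roi)) lst$short_per_roi <- unlist(lst$short_per_roi)
  if (!is.null(lst$isi_range_s)) lst$isi_range_s <- unlist(lst$isi_range_s)
  do.call(run_config, lst)
}
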