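#' Build a 4-AFC emotion-recognition trial schedule
#'
#' Practice trials first (one per emotion in natural speech by convention of
#' the task), then every emotion x condition x sentence stimulus exactly
#' once in seeded random order.
#'
#' @param emotions Character vector of emotion labels.
#' @param conditions Character vector of condition names.
#' @param sentences_per_cell Number of distinct sentences per emotion.
#' @param n_practice Number of practice trials preceding the test trials.
#' @param seed Integer seed for the trial order.
#' @return An object of class `trial_schedule` with a `trials` data.frame
#'   (`index`, `kind`, `emotion`, `condition`, `sentence`, `stimulus`) and
#'   attributes `session` and `seed`.
#' @export
make_afc_schedule <- function(emotions = c("angry", "happy", "sad", "unemotional"),
                              conditions = condition_names(),
                              sentences_per_cell = 5,
                              n_practice = 4,
                              seed = 1L) {
  stopifnot(length(emotions) >= 1, length(conditions) >= 1,
            sentences_per_cell >= 1)
  grid <- expand.grid(emotion = emotions, condition = conditions,
                      sentence = seq_len(sentences_per_cell),
                      stringsAsFactors = FALSE)
  ord <- with_seed(substream_seed(seed, "afc"), sample.int(nrow(grid)))
  test <- grid[ord, , drop = FALSE]
  practice <- data.frame(
    emotion = rep_len(emotions, n_practice),
    condition = "natural", sentence = 1L, stringsAsFactors = FALSE)
  trials <- rbind(
    if (n_practice > 0) cbind(kind = "practice", practice) else NULL,
    cbind(kind = "test", test))
  trials$index <- seq_len(nrow(trials))
  trials$stimulus <- sprintf("%s_s%d_%s", trials$emotion, trials$sentence,
                             gsub("\\+", "-", trials$condition))
  rownames(trials) <- NULL
  structure(list(trials = trials[, c("index", "kind", "emotion", "condition",
                                     "sentence", "stimulus")],
                 session = "afc", seed = seed),
            class = "trial_schedule")
}

#' Build an fNIRS block-design schedule
#'
#' Familiarisation trials first, then a seeded random interleaving of
#' `reps` repetitions of each experimental condition and `attention_reps`
#' repetitions of each attention stimulus. Inter-stimulus intervals are
#' drawn uniformly from `isi_range_s` and onsets accumulate durations + ISIs.
#'
#' @param experimental_conditions Condition labels (including the silent
#'   control).
#' @param reps Repetitions per experimental condition.
#' @param attention_stimuli Labels of the attention (tone-overlay) stimuli.
#' @param attention_reps Repetitions per attention stimulus.
#' @param n_familiarization Leading familiarisation trials.
#' @param isi_range_s Length-2 range for uniform ISI draws, seconds.
#' @param block_dur_s Stimulus block duration, seconds.
#' @param seed Integer seed.
#' @return A `trial_schedule` whose `trials` data.frame has columns `index`,
#'   `kind` (`familiarization`/`experimental`/`attention`), `condition`,
#'   `onset_s`, `duration_s`, `isi_s`.
#' @export
make_block_schedule <- function(experimental_conditions = c("angry", "happy",
                                                            "sad", "unemotional",
                                                            "control"),
                                reps = 20,
                                attention_stimuli = paste0("attention_", 1:5),
                                attention_reps = 2,
                                n_familiarization = 4,
                                isi_range_s = c(13, 23),
                                block_dur_s = 7.25,
                                seed = 1L) {
  stopifnot(isi_range_s[1] < isi_range_s[2], reps >= 0, attention_reps >= 0)
  main <- data.frame(
    kind = c(rep("experimental", length(experimental_conditions) * reps),
             rep("attention", length(attention_stimuli) * attention_reps)),
    condition = c(rep(experimental_conditions, each = reps),
                  rep(attention_stimuli, each = attention_reps)),
    stringsAsFactors = FALSE)
  sd_seed <- substream_seed(seed, "block")
  trials <- with_seed(sd_seed, {
    if (nrow(main) > 0) main <- main[sample.int(nrow(main)), , drop = FALSE]
    fam <- if (n_familiarization > 0) data.frame(
      kind = "familiarization",
      condition = rep_len(setdiff(experimental_conditions, "control"),
                          n_familiarization),
      stringsAsFactors = FALSE) else NULL
    tr <- rbind(fam, main)
    tr$index <- seq_len(nrow(tr))
    tr$duration_s <- block_dur_s
    tr$isi_s <- stats::runif(nrow(tr), isi_range_s[1], isi_range_s[2])
    tr$onset_s <- cumsum(c(0, (tr$duration_s + tr$isi_s)[-nrow(tr)])) +
      isi_range_s[1]
    tr
  })
  rownames(trials) <- NULL
  structure(list(trials = trials[, c("index", "kind", "condition", "onset_s",
                                     "duration_s", "isi_s")],
                 session = "nirs", seed = seed),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %s session, %d trials (seed %d)\n",
              x$session, nrow(x$trials), x$seed))
  print(utils::head(x$trials, 4))
  invisible(x)
}

#' Write / read a BIDS-style events table
#'
#' `write_events` serialises a block schedule as a tab-separated events file
#' with columns `onset`, `duration`, `trial_type`, `kind`; `read_events`
#' reads it back losslessly.
#'
#' @param schedule A `trial_schedule` from [make_block_schedule()], or a
#'   data.frame with `onset_s`, `duration_s`, `condition` columns.
#' @param path Output TSV path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   data.frame sorted by onset.
#' @export
write_events <- function(schedule, path) {
  tr <- if (inherits(schedule, "trial_schedule")) schedule$trials else schedule
  df <- if ("onset" %in% names(tr)) {
    data.frame(onset = tr$onset, duration = tr$duration,
               trial_type = tr$trial_type,
               kind = if ("kind" %in% names(tr)) tr$kind else "experimental")
  } else {
    data.frame(onset = tr$onset_s, duration = tr$duration_s,
               trial_type = tr$condition,
               kind = if ("kind" %in% names(tr)) tr$kind else "experimental")
  }
  utils::write.table(df[order(df$onset), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop("events file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df[order(df$onset), , drop = FALSE]
}
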