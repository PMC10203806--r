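#' Brain-behaviour model: accuracy predicting response amplitude
#'
#' Mixed model of first-level ROI amplitudes (restricted by the caller to
#' the conditions of interest, typically the F0-attenuated ones) on each
#' participant's recognition accuracy: fixed effects `0 + roi + roi:accuracy`
#' (per-ROI intercept and accuracy slope), participant random intercept.
#' Fit separately per chromophore; the accuracy slope per ROI is the
#' quantity of interest.
#'
#' @param roi_estimates Data.frame with `participant`, `roi`, `condition`,
#'   `chromophore`, `theta`.
#' @param accuracy Data.frame with `participant` and `accuracy` (one value
#'   per participant, e.g. the pre-session proportion correct).
#' @param chromophores Chromophores to model.
#' @return Data.frame with `chromophore`, `roi`, `slope`, `se`, `t`, `p`
#'   (normal approximation), one row per ROI and chromophore.
#' @export
brain_behavior_model <- function(roi_estimates, accuracy,
                                 chromophores = c("HbO", "HbR")) {
  if (stats::sd(accuracy$accuracy) < 1e-12)
    stop("accuracy is constant across participants; slopes undefined",
         call. = FALSE)
  df_all <- merge(roi_estimates, accuracy, by = "participant")
  out <- list()
  for (chrom in chromophores) {
    df <- df_all[df_all$chromophore == chrom, , drop = FALSE]
    if (!nrow(df)) next
    df$roi <- factor(df$roi)
    df$participant <- factor(df$participant)
    fit <- suppressMessages(
      lme4::lmer(theta ~ 0 + roi + roi:accuracy + (1 | participant),
                 data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))
    b <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    slope_idx <- grepl(":accuracy$", names(b))
    roi_lab <- sub("^roi", "", sub(":accuracy$", "", names(b)[slope_idx]))
    z <- b[slope_idx] / se[slope_idx]
    out[[chrom]] <- data.frame(
      chromophore = chrom, roi = roi_lab, slope = as.numeric(b[slope_idx]),
      se = se[slope_idx], t = as.numeric(z),
      p = 2 * stats::pnorm(-abs(z)), row.names = NULL,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' HbO-HbR difference magnitude and pair class
#'
#' The unsigned magnitude of the difference between paired HbO and HbR
#' estimates, with each pair classed as `negatively-correlated` when the
#' two estimates have opposite (nonzero) signs — the pattern expected of a
#' true cortical activation — and `positively-correlated` when they share a
#' sign; zero estimates give `degenerate`.
#'
#' @param theta_hbo,theta_hbr Numeric vectors of paired estimates.
#' @return Data.frame with `magnitude` and `pair_class`.
#' @export
hbo_hbr_difference <- function(theta_hbo, theta_hbr) {
  if (length(theta_hbo) != length(theta_hbr))
    stop("HbO and HbR estimates must be paired", call. = FALSE)
  ok <- is.finite(theta_hbo) & is.finite(theta_hbr)
  if (!all(ok)) message(sum(!ok), " incomplete pair(s) skipped")
  h_o <- theta_hbo[ok]; h_r <- theta_hbr[ok]
  cls <- ifelse(h_o == 0 | h_r == 0, "degenerate",
                ifelse(sign(h_o) != sign(h_r), "negatively-correlated",
                       "positively-correlated"))
  data.frame(magnitude = abs(h_o - h_r), pair_class = cls,
             stringsAsFactors = FALSE)
}

#' Simulate per-participant ROI amplitudes with an accuracy coupling
#'
#' Desk-scale generator for validating the brain-behaviour model: draws a
#' per-participant accuracy, then ROI amplitudes with participant random
#' intercepts and noise, adding `coupling * (accuracy - mean)` only in
#' `coupled_roi` (negative coupling mirrors the amplitude decrease with
#' increasing accuracy).
#'
#' @param n_participants Number of participants.
#' @param coupling Slope of amplitude on accuracy in the coupled ROI (on
#'   the HbO scale; HbR uses `hbr_ratio` times it).
#' @param coupled_roi ROI receiving the coupling.
#' @param base_amp Baseline HbO amplitude, µM.
#' @param participant_sd,noise_sd Random-intercept and residual SDs, µM.
#' @param hbr_ratio HbR/HbO ratio.
#' @param conditions Condition labels replicated per participant.
#' @param seed Integer seed.
#' @return List with `roi_estimates` (as consumed by
#'   [brain_behavior_model()]) and `accuracy`.
#' @export
simulate_brain_behavior <- function(n_participants = 22, coupling = -2,
                                    coupled_roi = "RSTG", base_amp = 1,
                                    participant_sd = 0.3, noise_sd = 0.4,
                                    hbr_ratio = -1 / 3,
                                    conditions = c("F0_happy", "F0_sad"),
                                    seed = 1L) {
  with_seed(substream_seed(seed, "bb"), {
    acc <- stats::runif(n_participants, 0.25, 0.95)
    rois <- roi_names()
    grid <- expand.grid(participant = seq_len(n_participants),
                        roi = rois, condition = conditions,
                        stringsAsFactors = FALSE)
    intercepts <- stats::rnorm(n_participants, 0, participant_sd)
    mu <- base_amp + intercepts[grid$participant] +
      ifelse(grid$roi == coupled_roi,
             coupling * (acc[grid$participant] - mean(acc)), 0)
    hbo <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    hbr <- mu * hbr_ratio + stats::rnorm(nrow(grid), 0, noise_sd * 0.5)
    roi_estimates <- rbind(
      data.frame(grid, chromophore = "HbO", theta = hbo,
                 stringsAsFactors = FALSE),
      data.frame(grid, chromophore = "HbR", theta = hbr,
                 stringsAsFactors = FALSE))
    list(roi_estimates = roi_estimates,
         accuracy = data.frame(participant = seq_len(n_participants),
                               accuracy = acc))
  })
}
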