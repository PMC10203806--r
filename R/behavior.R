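#' Cue-weighting choice model for 4-AFC responses
#'
#' Generative model of emotion-recognition responses: each trial's four
#' response log-odds start from a correct-response baseline for the
#' presented emotion; attenuating an informative cue subtracts its effect
#' from the correct-response log-odds, and attenuating F0 additionally
#' raises the log-odds of the "unemotional" alternative (the confusion
#' structure seen when pitch cues are uninformative). Participants get a
#' normally distributed ability intercept.
#'
#' @param baseline Named numeric: correct-response log-odds advantage per
#'   emotion in natural speech.
#' @param cue_effects Named numeric `c(F0 = , intensity = , rate = )`:
#'   reduction of the correct log-odds when that cue is attenuated.
#' @param unemotional_bias Added to the "unemotional" log-odds when F0 is
#'   attenuated.
#' @param participant_sd SD of the per-participant ability intercept.
#' @return Object of class `cue_weight_model`.
#' @export
cue_weight_model <- function(baseline = c(angry = 3.4, happy = 2.6,
                                          sad = 2.6, unemotional = 2.8),
                             cue_effects = c(F0 = 1.4, intensity = 0.3,
                                             rate = 0.1),
                             unemotional_bias = 1.3,
                             participant_sd = 0.4) {
  stopifnot(all(c("F0", "intensity", "rate") %in% names(cue_effects)))
  structure(list(baseline = baseline, cue_effects = cue_effects,
                 unemotional_bias = unemotional_bias,
                 participant_sd = participant_sd),
            class = "cue_weight_model")
}

# per-trial response probabilities under the cue-weighting model
cue_weight_probs <- function(model, emotion, cond_name, intercept = 0) {
  alts <- names(model$baseline)
  att <- condition(cond_name)$attenuated
  lo <- stats::setNames(rep(0, length(alts)), alts)
  lo[emotion] <- lo[emotion] + model$baseline[[emotion]] + intercept -
    sum(model$cue_effects[att])
  # uninformative pitch pulls responses toward "unemotional"; when the
  # presented emotion IS unemotional this lands on the correct response,
  # which is why unemotional recognition survives F0 attenuation
  if ("F0" %in% att && "unemotional" %in% alts)
    lo["unemotional"] <- lo["unemotional"] + model$unemotional_bias
  p <- exp(lo - max(lo))
  p / sum(p)
}

#' Simulate 4-AFC responses from the cue-weighting model
#'
#' Draws one multinomial response per trial and participant from the
#' softmax of the model's log-odds; participant intercepts are drawn once
#' per participant. Deterministic given the seed.
#'
#' @param schedule An AFC `trial_schedule` (from [make_afc_schedule()]) or a
#'   data.frame with `emotion` and `condition` columns (test trials).
#' @param model A [cue_weight_model()].
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed.
#' @param time Label for the assessment time (e.g. "pre", "post", "single").
#' @return Data.frame with `participant`, `trial`, `emotion`, `condition`,
#'   `sentence`, `response`, `correct`, `time`.
#' @export
simulate_behavior <- function(schedule, model = cue_weight_model(),
                              n_participants = 40, seed = 1L,
                              time = "single") {
  tr <- if (inherits(schedule, "trial_schedule")) {
    t0 <- schedule$trials
    t0[t0$kind %in% c("test", "experimental"), , drop = FALSE]
  } else schedule
  if (!"sentence" %in% names(tr)) tr$sentence <- 1L
  alts <- names(model$baseline)
  with_seed(substream_seed(seed, paste0("behav_", time)), {
    intercepts <- stats::rnorm(n_participants, 0, model$participant_sd)
    out <- vector("list", n_participants)
    for (p in seq_len(n_participants)) {
      resp <- character(nrow(tr))
      for (i in seq_len(nrow(tr))) {
        pr <- cue_weight_probs(model, tr$emotion[i], tr$condition[i],
                               intercepts[p])
        resp[i] <- sample(alts, 1, prob = pr)
      }
      out[[p]] <- data.frame(
        participant = p, trial = seq_len(nrow(tr)), emotion = tr$emotion,
        condition = tr$condition, sentence = tr$sentence, response = resp,
        correct = resp == tr$emotion, time = time, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Per-condition confusion matrices
#'
#' For each condition, the 4x4 matrix of response proportions with rows =
#' presented emotion (each row sums to 1) and columns = response
#' alternative.
#'
#' @param responses Data.frame from [simulate_behavior()] (needs `emotion`,
#'   `condition`, `response`).
#' @return Named list of matrices, one per condition.
#' @export
confusion_matrix <- function(responses) {
  if (!nrow(responses)) stop("no responses", call. = FALSE)
  alts <- sort(unique(c(responses$emotion, responses$response)))
  lapply(split(responses, responses$condition), function(g) {
    tab <- table(factor(g$emotion, alts), factor(g$response, alts))
    sweep(unclass(tab), 1, pmax(rowSums(tab), 1), `/`)
  })
}

#' Logistic mixed model of recognition accuracy
#'
#' Fits a GLMM with logit link to trial-level correctness, with the given
#' contrast coding of condition as fixed effects and uncorrelated random
#' intercepts and condition-contrast slopes per participant plus a random
#' intercept per sentence. The model is then simplified: random terms whose
#' fitted SD is below `sd_tol` are removed, and each remaining random term
#' must survive a likelihood-ratio test against the model without it.
#'
#' @param responses Data.frame with `correct`, `condition`, `participant`,
#'   `sentence` (and optionally further fixed-effect columns named in
#'   `extra_fixed`).
#' @param coding A [sliding_diff_coding()] / [treatment_coding()] object
#'   whose levels match the condition labels.
#' @param extra_fixed Character vector of additional fixed-effect columns
#'   (e.g. a pre/post indicator).
#' @param sd_tol Random-term SD below which the term is dropped.
#' @param lrt_alpha Significance level of the likelihood-ratio retention
#'   test.
#' @param max_slopes Random contrast slopes are only attempted when the
#'   data has at least this many participants (small designs go straight
#'   to intercepts).
#' @return Object of class `accuracy_glmm`: list with the final `fit`, a
#'   `coefficients` data.frame (log-odds scale), the `coding`, and the
#'   record of dropped random terms.
#' @export
fit_accuracy_glmm <- function(responses, coding = sliding_diff_coding(condition_names()),
                              extra_fixed = character(0),
                              sd_tol = 0.01, lrt_alpha = 0.05,
                              max_slopes = 8) {
  stopifnot(inherits(coding, "contrast_coding"))
  df <- responses
  if (!all(df$condition %in% coding$levels))
    stop("condition labels not covered by the coding", call. = FALSE)
  df$condition <- factor(df$condition, levels = coding$levels)
  cn <- paste0("c", seq_len(ncol(coding$coding)))
  for (j in seq_along(cn))
    df[[cn[j]]] <- coding$coding[as.integer(df$condition), j]
  fixed <- c(cn, extra_fixed)
  fixed_part <- paste(fixed, collapse = " + ")

  slope_terms <- if (length(unique(df$participant)) >= max_slopes)
    paste0("(0 + ", cn, " | participant)") else character(0)
  rand_terms <- c("(1 | participant)", "(1 | sentence)", slope_terms)

  fit_with <- function(terms) {
    fml <- stats::as.formula(paste("correct ~", fixed_part,
                                   if (length(terms)) "+" else "",
                                   paste(terms, collapse = " + ")))
    suppressMessages(suppressWarnings(
      lme4::glmer(fml, data = df, family = stats::binomial("logit"),
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))))
  }
  fit_glm <- function() stats::glm(
    stats::as.formula(paste("correct ~", fixed_part)),
    data = df, family = stats::binomial("logit"))

  term_sd <- function(fit) {
    vc <- lme4::VarCorr(fit)
    vapply(vc, function(m) sqrt(max(diag(m))), numeric(1))
  }

  dropped <- character(0)
  terms <- rand_terms
  fit <- fit_with(terms)
  # drop terms explaining almost no variance
  sds <- term_sd(fit)
  keep <- sds >= sd_tol
  if (!all(keep)) {
    dropped <- terms[!keep]
    terms <- terms[keep]
    fit <- if (length(terms)) fit_with(terms) else fit_glm()
  }
  # likelihood-ratio confirmation of each remaining random term
  if (length(terms) && inherits(fit, "merMod")) {
    for (tm in rev(terms)) {
      if (length(terms) == 0) break
      reduced_terms <- setdiff(terms, tm)
      reduced <- if (length(reduced_terms)) fit_with(reduced_terms) else fit_glm()
      ll_full <- as.numeric(stats::logLik(fit))
      ll_red <- as.numeric(stats::logLik(reduced))
      pval <- stats::pchisq(2 * (ll_full - ll_red), df = 1, lower.tail = FALSE)
      if (is.na(pval) || pval > lrt_alpha) {
        dropped <- c(dropped, tm)
        terms <- reduced_terms
        fit <- reduced
      }
    }
  }

  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  keep_co <- intersect(names(b), c("(Intercept)", fixed))
  coefs <- data.frame(term = keep_co, estimate = as.numeric(b[keep_co]),
                      se = se[keep_co],
                      z = as.numeric(b[keep_co] / se[keep_co]),
                      p = 2 * stats::pnorm(-abs(b[keep_co] / se[keep_co])),
                      row.names = NULL, stringsAsFactors = FALSE)
  # readable contrast names
  map <- stats::setNames(colnames(coding$coding), cn)
  coefs$term <- ifelse(coefs$term %in% names(map), map[coefs$term], coefs$term)
  structure(list(fit = fit, coefficients = coefs, coding = coding,
                 dropped = dropped),
            class = "accuracy_glmm")
}

#' @export
print.accuracy_glmm <- function(x, ...) {
  cat("<accuracy_glmm> fixed effects (log-odds):\n")
  print(x$coefficients)
  if (length(x$dropped))
    cat("dropped random terms:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
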