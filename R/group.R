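#' Second-level cell-means mixed model
#'
#' Fits, per chromophore, a linear mixed model to first-level ROI estimates
#' with a suppressed intercept and fixed cell means for every ROI x
#' condition combination (`0 + roi:condition`), a participant random
#' intercept and, by default, random condition coefficients per participant.
#' If the maximal random structure yields a singular fit it is simplified to
#' the random intercept alone (with a message). Influential rows can be
#' screened out first with [cooks_exclude()].
#'
#' @param roi_estimates Data.frame with `participant`, `roi`, `condition`,
#'   `chromophore`, `theta` (and optionally `se`), e.g. stacked
#'   `first_level$roi_estimates`.
#' @param chromophore Which chromophore to model.
#' @param condition_slopes Include random condition coefficients per
#'   participant.
#' @param exclude_influential Apply Cook's-distance screening (threshold
#'   `4/N`) before fitting.
#' @return Object of class `cellmeans_fit`: the lme4 fit plus the cell
#'   table from [cell_estimates()], the fixed-effect covariance, and the
#'   row indices excluded by the Cook's screen.
#' @export
fit_cellmeans_model <- function(roi_estimates, chromophore = "HbO",
                                condition_slopes = TRUE,
                                exclude_influential = FALSE) {
  df <- roi_estimates[roi_estimates$chromophore == chromophore, , drop = FALSE]
  if (!nrow(df)) stop("no rows for chromophore ", chromophore, call. = FALSE)
  if (length(unique(df$participant)) < 2)
    stop("need at least 2 participants", call. = FALSE)
  df$roi <- factor(df$roi)
  df$condition <- factor(df$condition)
  df$participant <- factor(df$participant)

  excluded <- integer(0)
  if (exclude_influential) {
    cx <- cooks_exclude(df, theta ~ 0 + roi:condition)
    excluded <- cx$excluded
    df <- cx$retained
  }

  fit <- NULL
  if (condition_slopes) {
    fit <- suppressMessages(tryCatch(
      lme4::lmer(theta ~ 0 + roi:condition + (1 | participant) +
                   (0 + condition | participant),
                 data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) NULL))
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
      message("maximal random structure singular; refitting with random intercept only")
      fit <- NULL
    }
  }
  if (is.null(fit)) {
    fit <- lme4::lmer(theta ~ 0 + roi:condition + (1 | participant),
                      data = df, REML = TRUE)
  }
  cells <- cell_estimates(fit)
  structure(list(fit = fit, cells = cells,
                 vcov = as.matrix(stats::vcov(fit)),
                 chromophore = chromophore, excluded = excluded,
                 data = df),
            class = "cellmeans_fit")
}

#' Extract per-cell estimates from a suppressed-intercept fit
#'
#' One row per ROI x condition cell: estimate, standard error, normal 95%
#' CI, t, and p for the test against zero (the purpose of suppressing the
#' intercept).
#'
#' @param fit An `lmerMod` with `0 + roi:condition` fixed effects (or a
#'   `cellmeans_fit`).
#' @return Data.frame with `roi`, `condition`, `estimate`, `se`, `ci_lo`,
#'   `ci_hi`, `t`, `p`, ordered as the fixed-effect coefficients.
#' @export
cell_estimates <- function(fit) {
  if (inherits(fit, "cellmeans_fit")) return(fit$cells)
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  nm <- names(b)
  roi <- sub("^roi", "", vapply(strsplit(nm, ":"), `[`, "", 1))
  cond <- sub("^condition", "", vapply(strsplit(nm, ":"), `[`, "", 2))
  data.frame(roi = roi, condition = cond, estimate = as.numeric(b),
             se = se, ci_lo = b - 1.96 * se, ci_hi = b + 1.96 * se,
             t = as.numeric(b / se), p = 2 * stats::pnorm(-abs(b / se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cellmeans_fit <- function(x, ...) {
  cat(sprintf("<cellmeans_fit> %s: %d cells, %d rows (%d excluded)\n",
              x$chromophore, nrow(x$cells), nrow(x$data), length(x$excluded)))
  print(utils::head(x$cells, 6))
  invisible(x)
}

#' Cook's distance for the fixed-effects regression
#'
#' Computes Cook's distance for every row from the fixed-effects (ordinary
#' least squares) regression implied by `formula`, i.e.
#' `D_i = e_i^2 h_i / (p s^2 (1 - h_i)^2)` with leverage `h_i` from the hat
#' matrix, and excludes rows with `D > threshold` (default `4/N`).
#'
#' @param data Model data.frame.
#' @param formula Fixed-effects formula (e.g. `theta ~ 0 + roi:condition`).
#' @param threshold Exclusion threshold; default `4 / nrow(data)`.
#' @return List with `retained` (data.frame), `excluded` (integer row
#'   indices), and `cooks_d` (the distances).
#' @export
cooks_exclude <- function(data, formula, threshold = NULL) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  n <- nrow(X)
  if (is.null(threshold)) threshold <- 4 / n
  qrX <- qr(X)
  p <- qrX$rank
  Q <- qr.Q(qrX)[, seq_len(p), drop = FALSE]
  h <- rowSums(Q^2)
  e <- as.numeric(qr.resid(qrX, y))
  s2 <- sum(e^2) / (n - p)
  perfect <- s2 <= 1e-20 * max(mean(y^2), 1)
  d <- if (perfect) rep(0, n) else e^2 * h / (p * s2 * (1 - h)^2)
  d[h >= 1 - 1e-10 & !perfect] <- Inf  # exact-leverage rows dominate the fit
  excl <- which(d > threshold)
  if (length(excl))
    message(length(excl), " influential row(s) excluded (Cook's D > ",
            signif(threshold, 3), ")")
  list(retained = data[setdiff(seq_len(n), excl), , drop = FALSE],
       excluded = excl, cooks_d = d)
}

#' Marginal and conditional R-squared for mixed models
#'
#' Variance-partition R2: marginal = fixed-effect variance over the sum of
#' fixed, random and residual variances; conditional adds the random-effect
#' variance to the numerator. For logit models the residual variance is the
#' latent-logistic `pi^2 / 3`.
#'
#' @param fit An `lmerMod` or `glmerMod` (logit) fit.
#' @return Named vector `c(marginal, conditional)`.
#' @export
nakagawa_r2 <- function(fit) {
  X <- lme4::getME(fit, "X")
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  var_e <- if (inherits(fit, "glmerMod")) {
    fam <- stats::family(fit)
    if (fam$family == "binomial" && fam$link == "logit") pi^2 / 3
    else stop("only logit GLMMs supported", call. = FALSE)
  } else attr(vc, "sc")^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}
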