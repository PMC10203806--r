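#' Canonical haemodynamic response function
#'
#' Difference-of-gammas kernel: response peak at 6 s, undershoot peak at
#' 16 s, undershoot-to-peak ratio 1/6, normalised to a unit peak.
#'
#' @param t_s Times in seconds (>= 0; negative times return 0).
#' @return HRF amplitudes at `t_s`.
#' @export
hrf_canonical <- function(t_s) {
  g <- function(t, peak_s, shape) {
    rate <- (shape - 1) / peak_s
    stats::dgamma(t, shape = shape, rate = rate)
  }
  h <- function(t) g(t, 6, 6) - (1 / 6) * g(t, 16, 16)
  peak <- max(h(seq(0, 12, by = 0.001)))
  out <- ifelse(t_s < 0, 0, h(pmax(t_s, 0)) / peak)
  out
}

#' Discrete-cosine drift basis
#'
#' Cosine regressors covering frequencies up to `cutoff_hz`: the number of
#' drift columns is `floor(2 * T * cutoff_hz)` for a recording of length `T`
#' seconds (the DCT component `j` has frequency `j / (2T)`).
#'
#' @param n Number of samples.
#' @param rate_hz Sampling rate.
#' @param cutoff_hz Highest drift frequency modelled.
#' @return Matrix of drift columns (possibly zero columns).
#' @export
dct_drift_basis <- function(n, rate_hz, cutoff_hz = 0.01) {
  T_s <- n / rate_hz
  K <- floor(2 * T_s * cutoff_hz)
  if (K < 1) return(matrix(numeric(0), nrow = n, ncol = 0))
  tt <- seq_len(n) - 1
  out <- vapply(seq_len(K), function(j) cos(pi * j * (2 * tt + 1) / (2 * n)),
                numeric(n))
  colnames(out) <- paste0("drift_", seq_len(K))
  out
}

#' Principal components of the short-channel signals
#'
#' All principal components of the centred short-channel matrix, each scaled
#' to unit variance; components with negligible variance (degenerate
#' channels) are dropped with a message.
#'
#' @param short_mat Time x short-channel matrix (one chromophore).
#' @param tol Relative variance below which a component is considered
#'   degenerate.
#' @return Time x component matrix of unit-variance scores.
#' @export
short_channel_components <- function(short_mat, tol = 1e-10) {
  stopifnot(is.matrix(short_mat), ncol(short_mat) >= 1)
  cen <- sweep(short_mat, 2, colMeans(short_mat), `-`)
  sv <- svd(cen)
  keep <- sv$d > max(sv$d) * sqrt(tol) & sv$d > 1e-12
  if (!any(keep)) {
    message("all short channels constant; no components retained")
    return(matrix(numeric(0), nrow = nrow(short_mat), ncol = 0))
  }
  if (sum(keep) < ncol(short_mat))
    message(sprintf("%d degenerate short-channel component(s) dropped",
                    ncol(short_mat) - sum(keep)))
  scores <- sv$u[, keep, drop = FALSE]
  scores <- sweep(scores, 2, apply(scores, 2, stats::sd), `/`)
  colnames(scores) <- paste0("sc_pc_", seq_len(ncol(scores)))
  scores
}

#' Build a first-level GLM design matrix
#'
#' One column per condition (3-s boxcar at each onset of that condition
#' convolved with the canonical HRF), a constant, discrete-cosine drift
#' columns up to `drift_cutoff_hz`, and any supplied short-channel principal
#' components.
#'
#' @param events Events data.frame (`onset`, `duration`, `trial_type`).
#' @param rate_hz Analysis sampling rate.
#' @param n Number of samples in the analysis series.
#' @param boxcar_s Boxcar length, seconds.
#' @param drift_cutoff_hz Drift modelling cut-off frequency.
#' @param short_components Optional time x component nuisance matrix.
#' @param conditions Condition labels to model (default: all `trial_type`
#'   values present).
#' @return Object of class `nirs_design`: list with the matrix `X`,
#'   `conditions`, and `rate_hz`.
#' @export
build_design <- function(events, rate_hz, n, boxcar_s = 3,
                         drift_cutoff_hz = 0.01, short_components = NULL,
                         conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(events$trial_type)
  ev <- events[events$trial_type %in% conditions, , drop = FALSE]
  if (nrow(ev) && any(ev$onset * rate_hz > n))
    stop("events beyond recording end", call. = FALSE)
  Xc <- if (length(conditions))
    condition_regressors(ev, rate_hz, n, boxcar_s, conditions)
  else matrix(numeric(0), n, 0)
  X <- cbind(Xc, constant = rep(1, n), dct_drift_basis(n, rate_hz, drift_cutoff_hz))
  if (!is.null(short_components) && ncol(short_components) > 0) {
    stopifnot(nrow(short_components) == n)
    X <- cbind(X, short_components)
  }
  if (qr(X)$rank < ncol(X))
    warning("design matrix is rank deficient")
  structure(list(X = X, conditions = conditions, rate_hz = rate_hz),
            class = "nirs_design")
}

#' Fit a GLM with lag-1 autoregressive prewhitening
#'
#' Iterative Cochrane-Orcutt-style prewhitening: an OLS fit provides
#' residuals, the AR(1) coefficient is estimated from their lag-1
#' autocorrelation, both sides are whitened with the exact AR(1) transform
#' (first row scaled by `sqrt(1 - rho^2)`), and the fit is repeated until
#' the coefficient stabilises (`|delta rho| < 1e-3`, at most `max_iter`
#' passes). Estimates and standard errors come from the whitened fit.
#'
#' @param y Response series (one channel, one chromophore).
#' @param design A [build_design()] object or plain design matrix.
#' @param rho Fix the AR(1) coefficient instead of estimating it (`rho = 0`
#'   reproduces OLS exactly).
#' @param max_iter Maximum prewhitening iterations.
#' @param tol Convergence tolerance on rho.
#' @return Object of class `ar1_glm`: coefficients and standard errors for
#'   every column, the condition subset, `rho`, residual `sigma2`, `dof`.
#' @export
fit_ar1_glm <- function(y, design, rho = NULL, max_iter = 10, tol = 1e-3) {
  X <- if (inherits(design, "nirs_design")) design$X else design
  conditions <- if (inherits(design, "nirs_design")) design$conditions else colnames(X)
  stopifnot(length(y) == nrow(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  n <- length(y)

  whiten <- function(v, r) c(sqrt(1 - r^2) * v[1], v[-1] - r * v[-n])
  whiten_mat <- function(M, r)
    rbind(sqrt(1 - r^2) * M[1, , drop = FALSE],
          M[-1, , drop = FALSE] - r * M[-n, , drop = FALSE])
  fit_at <- function(r) {
    yw <- whiten(y, r)
    Xw <- whiten_mat(X, r)
    qw <- qr(Xw)
    beta <- qr.coef(qw, yw)
    resw <- yw - Xw %*% beta
    dof <- n - ncol(X)
    sigma2 <- sum(resw^2) / dof
    XtXinv <- chol2inv(qr.R(qw))
    se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
    names(se) <- colnames(X)[qw$pivot]
    se <- se[colnames(X)]
    list(beta = beta, se = se, sigma2 = sigma2, dof = dof)
  }
  est_rho <- function(beta) {
    e <- as.numeric(y - X %*% beta)
    denom <- sum(e^2)
    if (denom <= 1e-20 * max(sum(y^2), 1)) return(0)  # perfect fit
    sum(e[-1] * e[-n]) / denom
  }

  if (!is.null(rho)) {
    f <- fit_at(rho)
    rho_hat <- rho
  } else {
    rho_hat <- 0
    f <- fit_at(0)
    for (i in seq_len(max_iter)) {
      r_new <- est_rho(f$beta)
      r_new <- max(-0.99, min(0.99, r_new))
      if (abs(r_new - rho_hat) < tol) { rho_hat <- r_new; break }
      rho_hat <- r_new
      f <- fit_at(rho_hat)
    }
    f <- fit_at(rho_hat)
  }
  structure(list(beta = stats::setNames(as.numeric(f$beta), colnames(X)),
                 se = f$se, conditions = conditions, rho = rho_hat,
                 sigma2 = f$sigma2, dof = f$dof),
            class = "ar1_glm")
}

#' @export
coef.ar1_glm <- function(object, ...) object$beta

#' @export
print.ar1_glm <- function(x, ...) {
  cat(sprintf("<ar1_glm> rho = %.3f, dof = %d\n", x$rho, x$dof))
  cond <- intersect(x$conditions, names(x$beta))
  print(data.frame(beta = x$beta[cond], se = x$se[cond]))
  invisible(x)
}

#' Standard-error-weighted ROI aggregation
#'
#' Pools channel-level condition estimates within each region of interest
#' using inverse-standard-error weights `w = 1/se` (or inverse-variance
#' `w = 1/se^2`): `theta = sum(w b) / sum(w)` with propagated standard error
#' `sqrt(sum(w^2 se^2)) / sum(w)`.
#'
#' @param channel_results Data.frame with columns `channel`, `chromophore`,
#'   `condition`, `beta`, `se`.
#' @param montage A `nirs_montage` mapping channels to ROIs.
#' @param weighting `"inv_se"` (default) or `"inv_var"`.
#' @return Data.frame with `roi`, `condition`, `chromophore`, `theta`, `se`,
#'   `n_channels`.
#' @export
roi_aggregate <- function(channel_results, montage,
                          weighting = c("inv_se", "inv_var")) {
  weighting <- match.arg(weighting)
  cr <- merge(channel_results,
              as.data.frame(montage)[, c("channel", "roi")], by = "channel")
  if (!nrow(cr)) stop("no channels map to the montage", call. = FALSE)
  agg <- do.call(rbind, lapply(
    split(cr, list(cr$roi, cr$condition, cr$chromophore), drop = TRUE),
    function(g) {
      w <- if (weighting == "inv_se") 1 / g$se else 1 / g$se^2
      data.frame(roi = g$roi[1], condition = g$condition[1],
                 chromophore = g$chromophore[1],
                 theta = sum(w * g$beta) / sum(w),
                 se = sqrt(sum(w^2 * g$se^2)) / sum(w),
                 n_channels = nrow(g), stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  agg
}

#' Run the full first-level analysis on one recording
#'
#' Resample to the analysis rate, convert to optical density and then to
#' chromophore concentrations (modified Beer-Lambert law), restrict to long
#' channels, extract short-channel principal components per chromophore,
#' build the HRF design with drift and nuisance columns, fit the AR(1)
#' prewhitened GLM per channel and chromophore, and pool estimates per ROI
#' weighted by standard error.
#'
#' @param recording A `nirs_recording`.
#' @param participant Participant identifier carried into the outputs.
#' @param target_rate_hz Analysis rate (down from the instrument rate).
#' @param boxcar_s Boxcar length, seconds.
#' @param drift_cutoff_hz Drift cut-off frequency.
#' @param ppf Partial pathlength factor for the Beer-Lambert step.
#' @param use_short_channels Include short-channel principal components as
#'   nuisance regressors.
#' @param weighting ROI pooling weights, see [roi_aggregate()].
#' @param conditions Conditions to model; defaults to the experimental
#'   trial types (familiarisation and attention trials are excluded).
#' @return Object of class `first_level`: list with `channel_results`,
#'   `roi_estimates`, `design`, `concentrations`, `participant`.
#' @export
fit_first_level <- function(recording, participant = 1L,
                            target_rate_hz = 0.6, boxcar_s = 3,
                            drift_cutoff_hz = 0.01, ppf = 0.1,
                            use_short_channels = TRUE,
                            weighting = "inv_se",
                            conditions = NULL) {
  stopifnot(inherits(recording, "nirs_recording"))
  rec <- if (target_rate_hz < recording$rate_hz)
    resample_recording(recording, target_rate_hz) else recording
  conc <- beer_lambert(to_optical_density(rec), ppf = ppf)
  events <- rec$events
  if (is.null(conditions)) {
    conditions <- if ("kind" %in% names(events))
      unique(events$trial_type[events$kind == "experimental"])
    else unique(events$trial_type)
  }
  long <- select_long_channels(rec$montage)
  short_ch <- rec$montage$channel[rec$montage$is_short]
  n <- nrow(conc$hbo)

  fits <- list()
  for (chrom in c("HbO", "HbR")) {
    cmat <- if (chrom == "HbO") conc$hbo else conc$hbr
    pcs <- if (use_short_channels && length(short_ch))
      short_channel_components(cmat[, short_ch, drop = FALSE]) else NULL
    des <- build_design(events, rec$rate_hz, n, boxcar_s = boxcar_s,
                        drift_cutoff_hz = drift_cutoff_hz,
                        short_components = pcs, conditions = conditions)
    for (ch in long$channel) {
      f <- fit_ar1_glm(cmat[, ch], des)
      fits[[length(fits) + 1L]] <- data.frame(
        channel = ch, chromophore = chrom, condition = conditions,
        beta = f$beta[conditions], se = f$se[conditions], rho = f$rho,
        dof = f$dof, stringsAsFactors = FALSE)
    }
  }
  channel_results <- do.call(rbind, fits)
  rownames(channel_results) <- NULL
  roi_estimates <- roi_aggregate(channel_results, long, weighting = weighting)
  roi_estimates <- cbind(participant = participant, roi_estimates)
  structure(list(channel_results = channel_results,
                 roi_estimates = roi_estimates,
                 concentrations = conc, participant = participant),
            class = "first_level")
}

#' @export
print.first_level <- function(x, ...) {
  cat(sprintf("<first_level> participant %s: %d channel fits, %d ROI estimates\n",
              as.character(x$participant), nrow(x$channel_results),
              nrow(x$roi_estimates)))
  invisible(x)
}

#' Grand-average epoch waveforms
#'
#' Cuts condition-locked epochs out of the concentration time courses,
#' baseline-corrects each epoch by its pre-onset mean, averages channels
#' within ROI and epochs within condition, and attaches a t-based 95%
#' confidence band across epochs.
#'
#' @param conc Output of [beer_lambert()] (or of the first-level pipeline's
#'   `concentrations` element).
#' @param events Events data.frame.
#' @param window Length-2 epoch window around onset, seconds.
#' @param conditions Conditions to epoch (default: all present).
#' @param conf Confidence level of the band.
#' @return Data.frame with `condition`, `roi`, `chromophore`, `time`,
#'   `mean`, `lo`, `hi`, `n_epochs`.
#' @export
epoch_average <- function(conc, events, window = c(-5, 30),
                          conditions = NULL, conf = 0.95) {
  rate <- conc$rate_hz
  long <- select_long_channels(conc$montage)
  if (is.null(conditions)) conditions <- unique(events$trial_type)
  i_pre <- round(window[1] * rate)
  i_post <- round(window[2] * rate)
  rel <- i_pre:i_post
  out <- list()
  for (chrom in c("HbO", "HbR")) {
    cmat <- if (chrom == "HbO") conc$hbo else conc$hbr
    for (roi in unique(long$roi)) {
      ch <- long$channel[long$roi == roi]
      sig <- rowMeans(cmat[, ch, drop = FALSE])
      for (cond in conditions) {
        ons <- events$onset[events$trial_type == cond]
        eps <- list()
        for (o in ons) {
          i0 <- round(o * rate)
          idx <- i0 + rel + 1L
          if (min(idx) < 1 || max(idx) > length(sig)) next
          ep <- sig[idx]
          ep <- ep - mean(ep[rel <= 0])
          eps[[length(eps) + 1L]] <- ep
        }
        if (!length(eps)) next
        em <- do.call(cbind, eps)
        m <- rowMeans(em)
        ne <- ncol(em)
        half <- if (ne > 1)
          stats::qt(1 - (1 - conf) / 2, ne - 1) * apply(em, 1, stats::sd) / sqrt(ne)
        else rep(0, length(m))
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, roi = roi, chromophore = chrom,
          time = rel / rate, mean = m, lo = m - half, hi = m + half,
          n_epochs = ne, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
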