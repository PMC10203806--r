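#' Sliding-difference contrast coding
#'
#' Factor coding whose regression coefficients estimate consecutive-level
#' differences `mu_{i+1} - mu_i`. Closed form: entry for level `i`, contrast
#' `j` is `-(k - j)/k` when `i <= j` and `j/k` otherwise. The defining
#' property is that the difference matrix (rows `e_{j+1} - e_j`) times this
#' coding is the identity.
#'
#' @param levels Either the number of levels `k` or a character vector of
#'   level names.
#' @return Object of class `contrast_coding`: list with `kind`, `levels`,
#'   and the k x (k-1) `coding` matrix.
#' @export
sliding_diff_coding <- function(levels) {
  lev <- if (is.numeric(levels) && length(levels) == 1)
    paste0("L", seq_len(levels)) else as.character(levels)
  k <- length(lev)
  if (k < 2) stop("need at least 2 levels", call. = FALSE)
  M <- matrix(0, k, k - 1,
              dimnames = list(lev, paste0(lev[-1], "-", lev[-k])))
  for (i in seq_len(k)) for (j in seq_len(k - 1)) {
    M[i, j] <- if (i <= j) -(k - j) / k else j / k
  }
  structure(list(kind = "sliding_difference", levels = lev, coding = M),
            class = "contrast_coding")
}

#' Treatment (dummy) contrast coding
#'
#' Column `j` indicates level `j + 1`; coefficients estimate differences
#' from the first (reference) level.
#'
#' @inheritParams sliding_diff_coding
#' @return A `contrast_coding`.
#' @export
treatment_coding <- function(levels) {
  lev <- if (is.numeric(levels) && length(levels) == 1)
    paste0("L", seq_len(levels)) else as.character(levels)
  k <- length(lev)
  if (k < 2) stop("need at least 2 levels", call. = FALSE)
  M <- matrix(0, k, k - 1, dimnames = list(lev, paste0(lev[-1], "-", lev[1])))
  for (j in seq_len(k - 1)) M[j + 1, j] <- 1
  structure(list(kind = "treatment", levels = lev, coding = M),
            class = "contrast_coding")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement: sort p ascending,
#' multiply by `m / rank`, take running minima from the largest rank down,
#' cap at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
fdr_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Linear contrast of cell estimates
#'
#' Estimates `w' theta` with standard error from the cell covariance
#' (diagonal `se^2` when a full covariance is not supplied), a normal-
#' approximation p-value, and a 95% CI. Difference contrasts should use
#' weights summing to zero.
#'
#' @param cells Data.frame of cell estimates with columns `estimate` and
#'   `se` (e.g. from [cell_estimates()]).
#' @param weights Numeric weight vector, one per row of `cells`.
#' @param vcov Optional covariance matrix of the cell estimates.
#' @param name Contrast label.
#' @return One-row data.frame of class `contrast_result`: `name`,
#'   `estimate`, `se`, `ci_lo`, `ci_hi`, `t`, `p`.
#' @export
contrast <- function(cells, weights, vcov = NULL, name = "contrast") {
  if (length(weights) != nrow(cells))
    stop("weights length must match number of cells", call. = FALSE)
  est <- sum(weights * cells$estimate)
  V <- if (is.null(vcov)) diag(cells$se^2, nrow = nrow(cells)) else vcov
  se <- sqrt(as.numeric(t(weights) %*% V %*% weights))
  tval <- if (se > 0) est / se else 0
  p <- 2 * stats::pnorm(-abs(tval))
  out <- data.frame(name = name, estimate = est, se = se,
                    ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
                    t = tval, p = p, stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Apply a family of planned contrasts with FDR correction
#'
#' Evaluates each weight vector with [contrast()] and appends
#' Benjamini-Hochberg adjusted p-values across the family.
#'
#' @param cells Cell-estimate data.frame (`estimate`, `se`).
#' @param weight_list Named list of weight vectors.
#' @param vcov Optional covariance of the cell estimates.
#' @return Data.frame with one row per contrast, including `p_fdr`.
#' @export
contrast_family <- function(cells, weight_list, vcov = NULL) {
  res <- do.call(rbind, lapply(names(weight_list), function(nm)
    contrast(cells, weight_list[[nm]], vcov = vcov, name = nm)))
  res$p_fdr <- fdr_bh(res$p)
  res
}
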