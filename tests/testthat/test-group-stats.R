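make_cell_data <- function(n_participants = 10, noise_sd = 0,
                           participant_sd = 0, seed = 1) {
  set.seed(seed)
  rois <- roi_names()
  conds <- c("angry", "happy", "sad", "unemotional", "control")
  mu <- outer(seq_along(rois), seq_along(conds), function(r, c) 0.2 * r + 0.1 * c)
  dimnames(mu) <- list(rois, conds)
  grid <- expand.grid(participant = seq_len(n_participants), roi = rois,
                      condition = conds, stringsAsFactors = FALSE)
  pint <- stats::rnorm(n_participants, 0, participant_sd)
  grid$theta <- mu[cbind(grid$roi, grid$condition)] + pint[grid$participant] +
    stats::rnorm(nrow(grid), 0, noise_sd)
  grid$chromophore <- "HbO"
  list(data = grid, mu = mu)
}

test_that("cell-means model returns exact cell means without noise", {
  cd <- make_cell_data(n_participants = 6)
  fit <- suppressMessages(fit_cellmeans_model(cd$data, condition_slopes = FALSE))
  expect_equal(nrow(fit$cells), 30)  # 6 ROIs x 5 conditions
  got <- fit$cells
  expect_lt(max(abs(got$estimate - cd$mu[cbind(got$roi, got$condition)])), 1e-8)
})

test_that("cell-means CIs attain nominal coverage over replicates", {
  covered <- total <- 0
  for (s in 1:40) {
    cd <- make_cell_data(n_participants = 22, noise_sd = 0.4,
                         participant_sd = 0.3, seed = s)
    fit <- suppressMessages(fit_cellmeans_model(cd$data))
    ce <- fit$cells
    truth <- cd$mu[cbind(ce$roi, ce$condition)]
    covered <- covered + sum(ce$ci_lo <= truth & truth <= ce$ci_hi)
    total <- total + nrow(ce)
  }
  expect_gte(covered / total, 0.90)
  expect_lte(covered / total, 0.99)
})

test_that("Cook's distance matches the brute-force leave-one-out definition", {
  cd <- make_cell_data(n_participants = 6)
  cx <- cooks_exclude(cd$data, theta ~ 0 + roi:condition)
  expect_length(cx$excluded, 0)

  # displaced row gets excluded
  cd2 <- make_cell_data(n_participants = 6, noise_sd = 0.1, seed = 3)
  cd2$data$theta[17] <- cd2$data$theta[17] + 10
  cx2 <- suppressMessages(cooks_exclude(cd2$data, theta ~ 0 + roi:condition))
  expect_true(17 %in% cx2$excluded)

  # brute force on a 10-row simple regression
  set.seed(9)
  df <- data.frame(x = stats::rnorm(10), y = stats::rnorm(10))
  cx3 <- suppressMessages(cooks_exclude(df, y ~ x, threshold = Inf))
  X <- cbind(1, df$x)
  yhat <- X %*% solve(crossprod(X), crossprod(X, df$y))
  p <- 2
  s2 <- sum((df$y - yhat)^2) / (10 - p)
  d_brute <- sapply(1:10, function(i) {
    Xi <- X[-i, ]; yi <- df$y[-i]
    yhat_i <- X %*% solve(crossprod(Xi), crossprod(Xi, yi))
    sum((yhat - yhat_i)^2) / (p * s2)
  })
  expect_equal(cx3$cooks_d, d_brute, tolerance = 1e-8)
  # and against the standard implementation
  expect_equal(cx3$cooks_d, unname(stats::cooks.distance(stats::lm(y ~ x, df))),
               tolerance = 1e-10)
})

test_that("BH adjustment matches the hand oracle and the reference routine", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))

  set.seed(10)
  for (i in 1:20) {
    p <- stats::runif(24)
    adj <- fdr_bh(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("BH controls the false-discovery proportion on global nulls", {
  set.seed(11)
  q <- 0.05
  fdp <- replicate(1000, {
    p <- stats::runif(24)
    mean(fdr_bh(p) <= q) # all discoveries are false under the global null
  })
  expect_lte(mean(fdp), q + 0.02)
})

test_that("sliding-difference coding has its closed form and defining property", {
  c2 <- sliding_diff_coding(2)
  expect_equal(unname(c2$coding[, 1]), c(-0.5, 0.5))

  for (k in 2:6) {
    ck <- sliding_diff_coding(k)
    D <- diff(diag(k)) # rows mu_{i+1} - mu_i
    expect_equal(D %*% ck$coding, diag(k - 1), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  # regression on noise-free cell means returns consecutive differences
  mu <- c(2, 1.5, 0.8, 0.7, 0.6)
  ck <- sliding_diff_coding(5)
  X <- cbind(1, ck$coding)
  b <- solve(crossprod(X), crossprod(X, mu))
  expect_equal(as.numeric(b[-1]), diff(mu), tolerance = 1e-12)

  tc <- treatment_coding(3)
  expect_equal(unname(tc$coding), rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_error(sliding_diff_coding(1), "2")
})

test_that("contrasts combine cells correctly and lateralisation is antisymmetric", {
  cd <- make_cell_data(n_participants = 8, noise_sd = 0.3,
                       participant_sd = 0.2, seed = 5)
  fit <- suppressMessages(fit_cellmeans_model(cd$data))
  ce <- fit$cells

  w0 <- rep(0, nrow(ce)); w0[3] <- 1; w0[3] <- 0
  expect_equal(contrast(ce, w0)$estimate, 0)
  expect_error(contrast(ce, c(1, -1)), "length")

  wlat <- ifelse(ce$roi == "RSTG", 1, ifelse(ce$roi == "LSTG", -1, 0)) / 5
  r1 <- contrast(ce, wlat, vcov = fit$vcov, name = "RSTG-LSTG")

  # swap the two STG ROIs in the data: the contrast flips sign exactly
  swapped <- cd$data
  swapped$roi[cd$data$roi == "RSTG"] <- "LSTG"
  swapped$roi[cd$data$roi == "LSTG"] <- "RSTG"
  fit2 <- suppressMessages(fit_cellmeans_model(swapped))
  ce2 <- fit2$cells
  wlat2 <- ifelse(ce2$roi == "RSTG", 1, ifelse(ce2$roi == "LSTG", -1, 0)) / 5
  r2 <- contrast(ce2, wlat2, vcov = fit2$vcov)
  expect_equal(r1$estimate, -r2$estimate, tolerance = 1e-8)

  fam <- contrast_family(ce, list(a = wlat, b = -wlat, c = w0),
                         vcov = fit$vcov)
  expect_equal(fam$p_fdr, fdr_bh(fam$p))
})

test_that("Nakagawa R2 recovers known variance partitions", {
  # no random variance: conditional == marginal == classical R2
  set.seed(12)
  n <- 2000
  x <- stats::rnorm(n)
  g <- rep(1:20, each = n / 20)
  y <- x + stats::rnorm(n)
  f <- suppressMessages(lme4::lmer(y ~ x + (1 | g),
                                   control = lme4::lmerControl(check.conv.singular = "ignore")))
  r2 <- nakagawa_r2(f)
  expect_lt(abs(r2[["marginal"]] - r2[["conditional"]]), 0.02)
  expect_lt(abs(r2[["marginal"]] - summary(stats::lm(y ~ x))$r.squared), 0.02)

  # sigma2_f = 1, sigma2_r = 1, sigma2_e = 2 -> marginal .25, conditional .5
  n <- 5000; ng <- 50
  g <- rep(seq_len(ng), each = n / ng)
  b <- stats::rnorm(ng)
  x <- stats::rnorm(n)
  y <- x + b[g] + stats::rnorm(n, 0, sqrt(2))
  f2 <- lme4::lmer(y ~ x + (1 | g))
  r22 <- nakagawa_r2(f2)
  expect_lt(abs(r22[["marginal"]] - 0.25), 0.05)
  expect_lt(abs(r22[["conditional"]] - 0.5), 0.05)

  # pure noise: both near zero
  y0 <- stats::rnorm(n)
  f0 <- suppressMessages(lme4::lmer(y0 ~ x + (1 | g),
                                    control = lme4::lmerControl(check.conv.singular = "ignore")))
  expect_lt(max(nakagawa_r2(f0)), 0.02)
})

test_that("HbO-HbR difference magnitude and pair classes follow the definition", {
  d <- hbo_hbr_difference(c(2, 1, 1), c(-1, 1, 0.5))
  expect_equal(d$magnitude, c(3, 0, 0.5))
  expect_equal(d$pair_class, c("negatively-correlated", "positively-correlated",
                               "positively-correlated"))
  expect_equal(hbo_hbr_difference(0, 0.5)$pair_class, "degenerate")
  expect_error(hbo_hbr_difference(1:2, 1), "paired")
  expect_message(hbo_hbr_difference(c(1, NA), c(-1, 2)), "skipped")
})

test_that("speech-vs-control contrast recovers the simulated difference", {
  mont <- tiny_montage()
  hits <- 0
  n_seeds <- 12
  for (s in 1:n_seeds) {
    roi_est <- do.call(rbind, lapply(1:8, function(p) {
      sched <- tiny_schedule(reps = 4, seed = s * 100 + p)
      rec <- simulate_recording(mont, sched, default_truth(),
                                noise_config(), seed = s * 100 + p)
      fit_first_level(rec, participant = p)$roi_estimates
    }))
    fit <- suppressMessages(fit_cellmeans_model(roi_est))
    ce <- fit$cells
    w <- ifelse(ce$roi == "RSTG" & ce$condition != "control", 1 / 4,
                ifelse(ce$roi == "RSTG" & ce$condition == "control", -1, 0))
    r <- contrast(ce, w, vcov = fit$vcov)
    true_diff <- default_truth()$beta["angry", "RSTG"]
    hits <- hits + (r$ci_lo <= true_diff && true_diff <= r$ci_hi)
  }
  expect_gte(hits / n_seeds, 0.8)
})
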