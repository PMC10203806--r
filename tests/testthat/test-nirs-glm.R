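test_that("polyphase resampling preserves content and length", {
  # constant stays constant
  const <- resample_poly(rep(3, 1300), 3, 13)
  expect_equal(const, rep(3, 300), tolerance = 1e-3)
  expect_equal(length(const), floor(1300 * 3 / 13))

  # slow sinusoid amplitude preserved within 1%
  t <- seq(0, 1000, by = 1 / 2.6)
  x <- sin(2 * pi * 0.05 * t)
  y <- resample_poly(x, 3, 13)
  mid <- 50:(length(y) - 50)
  ref <- sin(2 * pi * 0.05 * (seq_along(y) - 1) / 0.6)
  expect_lt(abs(stats::sd(y[mid]) / stats::sd(ref[mid]) - 1), 0.01)
  expect_lt(sqrt(mean((y[mid] - ref[mid])^2)), 0.01)

  mont <- tiny_montage()
  ev <- schedule_events(tiny_schedule(reps = 2, seed = 1))
  rec <- simulate_recording(mont, tiny_schedule(reps = 2, seed = 1),
                            default_truth(), noise_config(), seed = 1)
  n_in <- nrow(rec$intensity[[1]])
  res <- resample_recording(rec, 0.6)
  expect_equal(res$rate_hz, 0.6)
  expect_lte(abs(nrow(res$intensity[[1]]) - floor(n_in * 3 / 13)), 1)
  expect_error(resample_recording(res, 2.6), "below")
})

test_that("optical density has its defining properties", {
  mont <- tiny_montage()
  rec <- simulate_recording(mont, tiny_schedule(reps = 2, seed = 2),
                            default_truth(), noise_config(), seed = 2)

  # constant intensity -> OD identically zero
  rec_const <- rec
  rec_const$intensity <- lapply(rec$intensity, function(m) {
    m[] <- rep(colMeans(m), each = nrow(m)); m
  })
  od0 <- to_optical_density(rec_const)
  expect_true(all(abs(od0$od[["760"]]) < 1e-12))

  # scale invariance
  rec_scaled <- rec
  rec_scaled$intensity <- lapply(rec$intensity, function(m) m * 7)
  expect_equal(to_optical_density(rec)$od[["850"]],
               to_optical_density(rec_scaled)$od[["850"]], tolerance = 1e-12)

  # hand-computed two-sample example: I = (1, e^-1)
  rec_toy <- rec
  rec_toy$intensity <- lapply(rec$intensity, function(m) {
    mm <- m[1:2, 1, drop = FALSE]; mm[, 1] <- c(1, exp(-1)); mm
  })
  od <- to_optical_density(rec_toy)$od[["760"]][, 1]
  expect_equal(od, c(log((1 + exp(-1)) / 2), 1 + log((1 + exp(-1)) / 2)),
               tolerance = 1e-12, ignore_attr = TRUE)

  rec_bad <- rec
  rec_bad$intensity[["760"]][5, 2] <- -1
  expect_error(to_optical_density(rec_bad), rec$montage$channel[2])
})

test_that("Beer-Lambert conversion is the algebraic inverse with documented scaling", {
  mont <- tiny_montage()
  rec <- simulate_recording(mont, tiny_schedule(reps = 2, seed = 3),
                            default_truth(), noise_config(), seed = 3)
  od <- to_optical_density(rec)

  od0 <- od
  od0$od <- lapply(od$od, function(m) { m[] <- 0; m })
  c0 <- beer_lambert(od0)
  expect_true(all(c0$hbo == 0) && all(c0$hbr == 0))

  # halving ppf doubles both chromophore amplitudes
  c1 <- beer_lambert(od, ppf = 0.1)
  c2 <- beer_lambert(od, ppf = 0.05)
  expect_equal(c2$hbo, 2 * c1$hbo, tolerance = 1e-9)
  expect_equal(c2$hbr, 2 * c1$hbr, tolerance = 1e-9)

  expect_error(extinction_coefficients(c(760, 900)), "tabulated")
})

test_that("long-channel selection applies inclusive distance bounds", {
  m <- make_montage()
  kept <- select_long_channels(m)
  expect_equal(nrow(kept), 60)

  m2 <- m
  m2$distance_mm[!m2$is_short][1:3] <- c(20, 19.9, 40)
  kept2 <- select_long_channels(m2)
  expect_true(all(c(20, 40) %in% kept2$distance_mm))
  expect_false(any(kept2$distance_mm == 19.9))

  m3 <- m
  m3$distance_mm[!m3$is_short] <- 50
  expect_error(select_long_channels(m3), "retained")
})

test_that("canonical HRF peaks at 6 s with positive net response", {
  tt <- seq(0, 32, by = 0.001)
  h <- hrf_canonical(tt)
  expect_lt(abs(tt[which.max(h)] - 6), 0.1)
  expect_equal(max(h), 1, tolerance = 1e-9)
  expect_equal(hrf_canonical(0), 0)
  expect_gt(sum(h) * 0.001, 0)
  # undershoot: negative tail after ~10 s
  expect_lt(min(h[tt > 10]), 0)
})

test_that("design matrix has event linearity, the DCT drift count, and appended PCs", {
  rate <- 0.6
  n <- round(3000 * rate)
  ev2 <- data.frame(onset = c(20, 200), duration = 7.25,
                    trial_type = "speech")
  X2 <- build_design(ev2, rate, n)
  Xa <- build_design(ev2[1, ], rate, n)
  Xb <- build_design(ev2[2, ], rate, n)
  expect_equal(X2$X[, "speech"], Xa$X[, "speech"] + Xb$X[, "speech"],
               tolerance = 1e-12)

  # 3000 s at cutoff 0.01 Hz -> floor(2*3000*0.01) = 60 drift columns
  drift_cols <- grep("^drift_", colnames(X2$X))
  expect_equal(length(drift_cols), 60)
  expect_true("constant" %in% colnames(X2$X))

  X0 <- build_design(ev2[0, ], rate, n, conditions = character(0))
  expect_false(any(grepl("speech", colnames(X0$X))))

  pcs <- matrix(stats::rnorm(n * 2), n, 2,
                dimnames = list(NULL, c("sc_pc_1", "sc_pc_2")))
  Xp <- build_design(ev2, rate, n, short_components = pcs)
  expect_true(all(c("sc_pc_1", "sc_pc_2") %in% colnames(Xp$X)))

  expect_error(build_design(data.frame(onset = 4000, duration = 7,
                                       trial_type = "speech"), rate, n),
               "beyond")
})

test_that("short-channel PCA yields orthonormal scores that span the data", {
  set.seed(5)
  n <- 400
  latent <- cbind(sin(seq_len(n) / 10), cos(seq_len(n) / 23))
  S <- latent %*% matrix(stats::rnorm(16), 2, 8) +
    matrix(stats::rnorm(n * 8, sd = 0.1), n, 8)
  pcs <- short_channel_components(S)
  G <- crossprod(pcs) / (n - 1)
  expect_equal(G, diag(ncol(pcs)), tolerance = 1e-8, ignore_attr = TRUE)

  # all PCs reconstruct the centred data
  cen <- sweep(S, 2, colMeans(S))
  proj <- pcs %*% solve(crossprod(pcs), crossprod(pcs, cen))
  expect_lt(max(abs(proj - cen)), 1e-9)

  # identical channels collapse to one component
  S1 <- matrix(rep(sin(seq_len(n) / 7), 8), n, 8)
  expect_message(p1 <- short_channel_components(S1), "dropped")
  expect_equal(ncol(p1), 1)
})

test_that("AR(1) GLM recovers exactly without noise and matches OLS at rho = 0", {
  set.seed(6)
  n <- 300
  X <- cbind(a = sin(seq_len(n) / 9), b = cos(seq_len(n) / 31),
             constant = 1)
  beta <- c(2, -1, 0.5)
  y <- as.numeric(X %*% beta)
  f <- fit_ar1_glm(y, X)
  expect_lt(max(abs(f$beta - beta)), 1e-10)
  expect_lt(abs(f$rho), 1e-6)

  # forcing rho = 0 reproduces OLS exactly
  yn <- y + stats::rnorm(n)
  f0 <- fit_ar1_glm(yn, X, rho = 0)
  ols <- stats::lm.fit(X, yn)
  expect_equal(f0$beta, ols$coefficients, tolerance = 1e-12)
  sm <- summary(stats::lm(yn ~ 0 + X))
  expect_equal(unname(f0$se), unname(sm$coefficients[, "Std. Error"]),
               tolerance = 1e-9)

  Xbad <- cbind(X, a2 = X[, "a"])
  expect_error(fit_ar1_glm(yn, Xbad), "collinear")
})

test_that("AR(1) coefficient and uncertainty are estimated consistently", {
  set.seed(7)
  n <- 800
  X <- cbind(reg = as.numeric(scale(sin(seq_len(n) / 17))), constant = 1)
  rhos <- betas <- ses <- numeric(60)
  for (s in 1:60) {
    e <- as.numeric(stats::arima.sim(list(ar = 0.6), n, sd = 1))
    y <- as.numeric(X %*% c(1, 0)) + e
    f <- fit_ar1_glm(y, X)
    rhos[s] <- f$rho; betas[s] <- f$beta["reg"]; ses[s] <- f$se["reg"]
  }
  expect_lt(abs(mean(rhos) - 0.6), 0.05)
  expect_lt(abs(stats::sd(betas) / mean(ses) - 1), 0.15)
})

test_that("ROI aggregation implements inverse-SE weighting", {
  m <- tiny_montage()
  long <- m[!m$is_short, ]
  cr <- data.frame(channel = rep(long$channel[1], 2),
                   chromophore = "HbO", condition = c("a", "a"),
                   beta = c(1, 3), se = c(1, 1))
  cr$channel <- long$channel[1:2]
  m2 <- m
  m2$roi <- "LSTG"
  agg <- roi_aggregate(cr, m2)
  expect_equal(agg$theta, 2)

  cr$se <- c(1, 1e6)
  agg2 <- roi_aggregate(cr, m2)
  expect_lt(abs(agg2$theta - 1), 1e-3)

  single <- roi_aggregate(cr[1, ], m2)
  expect_equal(single$theta, cr$beta[1])
  expect_equal(single$se, cr$se[1])
})

test_that("first-level pipeline is linear, channel-order invariant and I0 invariant", {
  mont <- tiny_montage()
  sched <- tiny_schedule(reps = 4, seed = 8)
  truth1 <- default_truth()
  truth2 <- default_truth(stg_amp = 2, frontal_amp = 0.4)

  r1 <- fit_first_level(simulate_recording(mont, sched, truth1, noise_off(),
                                           seed = 8))$roi_estimates
  r2 <- fit_first_level(simulate_recording(mont, sched, truth2, noise_off(),
                                           seed = 8))$roi_estimates
  expect_equal(r2$theta, 2 * r1$theta, tolerance = 1e-6)

  rec <- simulate_recording(mont, sched, truth1, noise_config(), seed = 9)
  rec_perm <- rec
  perm <- rev(seq_len(nrow(mont)))
  rec_perm$montage <- rec$montage[perm, ]
  rec_perm$intensity <- lapply(rec$intensity, function(m) m[, perm])
  a <- fit_first_level(rec)$roi_estimates
  b <- fit_first_level(rec_perm)$roi_estimates
  expect_equal(a[order(a$roi, a$condition, a$chromophore), c("theta", "se")],
               b[order(b$roi, b$condition, b$chromophore), c("theta", "se")],
               tolerance = 1e-9, ignore_attr = TRUE)

  rec_i0 <- simulate_recording(mont, sched, truth1, noise_config(), seed = 9,
                               baseline_intensity = 5)
  c_est <- fit_first_level(rec_i0)$roi_estimates
  expect_equal(a$theta, c_est$theta, tolerance = 1e-9)
})

test_that("epoch averages are baseline-corrected with coherent uncertainty", {
  mont <- tiny_montage()
  # widely spaced events so epochs do not overlap the neighbouring response
  ev <- data.frame(onset = seq(40, 400, by = 60), duration = 7.25,
                   trial_type = "angry")
  conc <- simulate_concentrations(mont, ev, default_truth(), noise_off(),
                                  seed = 10, duration_s = 470)
  ga <- epoch_average(conc, ev, conditions = "angry")
  one <- ga[ga$roi == "LSTG" & ga$chromophore == "HbO", ]
  # identical (noise-free) epochs: zero-width CI
  expect_lt(max(one$hi - one$lo), 1e-9)
  # baseline window mean is zero after correction
  expect_lt(abs(mean(one$mean[one$time <= 0])), 1e-9)
  # noise-free peak equals the unit-peak regressor amplitude
  expect_equal(max(one$mean), default_truth()$beta["angry", "LSTG"],
               tolerance = 0.05)
})
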