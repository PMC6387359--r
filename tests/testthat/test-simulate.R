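test_that("noiseless single-state heart rate stays at its setpoint", {
  cfg <- sim_config(
    days = 1, protocol = tibble::tibble(state = "rest", duration_s = 120),
    hr_noise_sd = 0, accel_noise_sd = 0, eda_noise_sd = 0,
    temp_noise_sd = 0, humidity_noise_sd = 0, amp_jitter_sd = 0)
  rec <- simulate_recording(cfg, seed = 1)
  expect_equal(rec$streams$hr$hr_bpm, rep(70, 120))
})

test_that("identical seeds give bit-identical recordings", {
  a <- short_recording(seed = 11)
  b <- short_recording(seed = 11)
  expect_identical(a$streams, b$streams)
  expect_identical(a$labels, b$labels)
  c <- short_recording(seed = 12)
  expect_false(identical(a$streams$hr, c$streams$hr))
})

test_that("default protocol emits the eight segments in order with stated durations", {
  rec <- simulate_recording(sim_config(days = 1), seed = 3)
  proto <- default_protocol()
  seg <- rle(rec$labels$segment)
  expect_equal(seg$values, seq_len(8))
  expect_equal(seg$lengths, proto$duration_s)
  # segment states match the protocol (the alternating block contains both)
  for (i in seq_len(8)) {
    states <- unique(rec$labels$state[rec$labels$segment == i])
    if (proto$state[i] == "run_walk") {
      expect_setequal(states, c("walk", "run"))
    } else {
      expect_equal(states, proto$state[i])
    }
  }
})

test_that("semi-Markov occupancy matches the analytic stationary distribution", {
  P <- matrix(c(0, .5, .5,
                .3, 0, .7,
                .6, .4, 0), 3, 3, byrow = TRUE)
  rownames(P) <- colnames(P) <- c("rest", "walk", "run")
  dwell <- c(rest = 20, walk = 20, run = 20)
  # embedded-chain stationary distribution (left eigenvector); equal dwell
  # means make the time occupancy equal to it
  e <- eigen(t(P))
  pi_s <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_s <- pi_s / sum(pi_s)
  cfg <- sim_config(days = 10, transition = P, dwell_mean_s = dwell,
                    hr_setpoint = c(rest = 70, walk = 100, run = 150),
                    accel_amp = c(rest = .05, walk = .5, run = 1.2),
                    accel_freq = c(rest = .3, walk = 1.8, run = 2.8),
                    eda_gain = c(rest = 0, walk = .5, run = 2))
  rec <- simulate_recording(cfg, seed = 5)
  occ <- table(factor(rec$labels$state, levels = rownames(P)))
  occ <- as.numeric(occ) / sum(occ)
  # 3 Monte-Carlo standard errors on the occupancy fractions; effective
  # sample size is the number of dwell segments, not label seconds
  n_seg <- sum(rle(rec$labels$state)$lengths > 0)
  se <- sqrt(pi_s * (1 - pi_s) / n_seg)
  expect_true(all(abs(occ - pi_s) <= 3 * se + 0.02))
})

test_that("per-state accelerometer variance orders rest < walk < run", {
  rec <- short_recording(seed = 2)
  acc <- rec$streams$ankle_accel
  st <- rec$labels$state[findInterval(acc$timestamp_s, rec$labels$timestamp_s)]
  v <- tapply(acc$ax, st, var)
  expect_lt(v[["rest"]], v[["walk"]])
  expect_lt(v[["walk"]], v[["run"]])
})

test_that("streams are gap-free and strictly increasing in time", {
  rec <- short_recording(seed = 4)
  for (nm in names(rec$streams)) {
    d <- diff(rec$streams[[nm]]$timestamp_s)
    expect_true(all(d > 0))
    expect_lt(max(d) / min(d), 1 + 1e-8)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(days = 0), "positive")
  expect_error(sim_config(protocol = tibble::tibble(state = "rest",
                                                    duration_s = -5)),
               "positive")
  P <- matrix(c(.5, .4, 0, 1), 2)
  expect_error(
    sim_config(transition = P, dwell_mean_s = c(a = 10, b = 10)),
    "sum to 1")
})

test_that("planted all-zero model with zero noise gives a constant target", {
  rec <- short_recording(seed = 6)
  pm <- planted_model(groups = list(), hr_ar = 0, intercept = 75, noise_sd = 0)
  out <- plant_linear_response(rec, pm, seed = 1, window = 5, dh = 10)
  expect_true(all(out$streams$hr$hr_bpm == 75))
  expect_length(attr(out, "true_support"), 0)
})

test_that("planted single-feature group correlates perfectly with its feature", {
  rec <- short_recording(seed = 6)
  pm <- planted_model(groups = list(humidity = 1), hr_ar = 0, intercept = 80,
                      noise_sd = 0)
  out <- plant_linear_response(rec, pm, seed = 1, window = 5, dh = 10)
  d <- build_design(out, dh = 10, window = 5)
  expect_equal(abs(cor(d$y, d$humidity__mean)), 1, tolerance = 1e-10)
  expect_equal(attr(out, "true_support"), "humidity")
})

test_that("OLS on the full design recovers planted coefficients within 3 SE", {
  cfg <- recovery_config(days = 1, day_scale = 50)   # one long day, ~5000 rows
  rec <- simulate_recording(cfg, seed = 8)
  pm <- recovery_planted(snr = 10, hr_ar = 0.5)
  rec <- plant_linear_response(rec, pm, seed = 8, window = 5, dh = 10)
  d <- build_design(rec, dh = 10, window = 5)
  std <- standardize_design(d)
  df <- data.frame(y = std$y * std$y_scale + std$y_center, std$Z)
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  # planted: variance features of both accelerometers, lagged HR
  for (cn in c("wrist_accel__ax_var", "ankle_accel__ax_var")) {
    est <- sm[cn, "Estimate"]; se <- sm[cn, "Std. Error"]
    expect_lt(abs(est - 2), 3 * se)
  }
  # the AR coefficient multiplies the raw lagged response; on the
  # standardized column the true coefficient is hr_ar * sd(hr__lag)
  expect_lt(abs(sm["hr__lag", "Estimate"] - 0.5 * sd(d$hr__lag)),
            3 * sm["hr__lag", "Std. Error"])
  expect_error(
    plant_linear_response(rec, planted_model(groups = list(nope = 1)),
                          seed = 1),
    "not present")
})
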