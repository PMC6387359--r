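# short protocols / recordings shared across test files

short_protocol <- function() {
  tibble::tibble(state = c("walk", "rest", "run", "exercise"),
                 duration_s = c(60, 60, 60, 60))
}

short_recording <- function(days = 2, seed = 1, ...) {
  cfg <- sim_config(days = days, protocol = short_protocol(),
                    rates_hz = c(body_temp = 4, env_temp = 1, humidity = 1,
                                 wrist_accel = 32, ankle_accel = 32,
                                 eda = 4, hr = 1), ...)
  simulate_recording(cfg, seed = seed)
}

# semi-Markov config used by the support-recovery harness: four activity
# states, EDA decoupled from activity so the non-planted sensors are
# genuinely irrelevant, both accelerometers at 32 Hz
recovery_config <- function(days = 3, day_scale = 20) {
  P <- matrix(1 / 3, 4, 4); diag(P) <- 0
  rownames(P) <- colnames(P) <- c("rest", "walk", "run", "exercise")
  sim_config(days = days, transition = P,
             dwell_mean_s = c(rest = 30, walk = 25, run = 25, exercise = 22) *
               day_scale / 20,
             eda_gain = c(rest = 0, walk = 0, run = 0, exercise = 0),
             amp_jitter_sd = 0.2,
             rates_hz = c(body_temp = 4, env_temp = 1, humidity = 1,
                          wrist_accel = 32, ankle_accel = 32, eda = 4, hr = 1))
}

# planted model on the accelerometer variance features plus lagged HR
recovery_planted <- function(snr = 10, hr_ar = 0.6) {
  v <- rep(0, 21); v[c(2, 8, 14)] <- 2    # per-axis variance features
  planted_model(groups = list(wrist_accel = v, ankle_accel = v),
                hr_ar = hr_ar, intercept = 90, snr = snr)
}
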