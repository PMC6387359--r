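#' Configuration for the synthetic multimodal recording generator
#'
#' The generator emulates a multi-day exercise protocol on a single subject:
#' each day the subject walks for 10 min, alternates walking and running
#' laps for 20 min, rests 10 min, performs two 15 min exercise sessions
#' separated by 5 min of rest, then walks twice more for 10 min each.
#' Activity states drive state-dependent sinusoidal accelerometer
#' waveforms, first-order heart-rate relaxation towards per-state
#' setpoints, slowly drifting state-coupled electrodermal activity, and
#' near-constant ambient/skin temperatures and humidity.
#'
#' Instead of the fixed protocol, a semi-Markov schedule can be requested by
#' supplying `transition` (a row-stochastic matrix over the four states) and
#' `dwell_mean_s` (mean exponential dwell time per state).
#'
#' @param days number of recording days (each an independent realization).
#' @param protocol tibble with columns `state`, `duration_s`; the default is
#'   the eight-segment protocol above. The composite `run_walk` state is
#'   expanded into alternating walk/run laps of `walk_lap_s`/`run_lap_s`.
#' @param transition,dwell_mean_s optional semi-Markov schedule (replaces
#'   `protocol` when both are given): 4x4 row-stochastic matrix and named
#'   mean dwell times (s) over states `rest`, `walk`, `run`, `exercise`.
#' @param accel_amp,accel_freq named per-state accelerometer amplitude (g)
#'   and dominant frequency (Hz). The exercise waveform alternates bursts
#'   of two frequencies (`exercise_freq2`), `burst_s` seconds each.
#' @param exercise_freq2,burst_s second exercise frequency (Hz), burst
#'   duration (s).
#' @param wrist_scale wrist amplitude relative to ankle.
#' @param accel_noise_sd accelerometer white-noise sd (g).
#' @param amp_jitter_sd lognormal sd of the slow within-state intensity
#'   modulation, drawn independently per sensor every `jitter_block_s`
#'   seconds (movement intensity fluctuates within an activity, and wrist
#'   and ankle intensities are not perfectly coupled).
#' @param jitter_block_s block length (s) of the intensity modulation.
#' @param hr_setpoint named per-state HR setpoints (bpm).
#' @param hr_tau HR relaxation time constant (s).
#' @param hr_noise_sd HR observation noise sd (bpm).
#' @param hr_init initial HR (bpm); defaults to the first state's setpoint.
#' @param eda_baseline,eda_drift,eda_gain,eda_tau,eda_noise_sd tonic EDA
#'   baseline (uS), linear drift (uS/s), per-state additive arousal gains
#'   (uS), response time constant (s) and noise sd (uS).
#' @param body_temp_c,env_temp_c,humidity_pct means of the near-constant
#'   channels; `temp_noise_sd`, `humidity_noise_sd` their noise sds.
#' @param temp_noise_sd,humidity_noise_sd noise sds for temperatures (deg C)
#'   and humidity (%RH).
#' @param rates_hz named sampling rates per modality.
#' @param walk_lap_s,run_lap_s walk/run lap durations (s) inside the
#'   alternating block.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(days = 4,
                       protocol = default_protocol(),
                       transition = NULL,
                       dwell_mean_s = NULL,
                       accel_amp = c(rest = 0.05, walk = 0.5, run = 1.2, exercise = 0.8),
                       accel_freq = c(rest = 0.3, walk = 1.8, run = 2.8, exercise = 0.9),
                       exercise_freq2 = 1.3,
                       burst_s = 10,
                       wrist_scale = 0.6,
                       accel_noise_sd = 0.05,
                       amp_jitter_sd = 0.05,
                       jitter_block_s = 10,
                       hr_setpoint = c(rest = 70, walk = 100, run = 150, exercise = 130),
                       hr_tau = 30,
                       hr_noise_sd = 1,
                       hr_init = NULL,
                       eda_baseline = 5,
                       eda_drift = 1e-4,
                       eda_gain = c(rest = 0, walk = 0.5, run = 2, exercise = 3),
                       eda_tau = 60,
                       eda_noise_sd = 0.05,
                       body_temp_c = 33,
                       env_temp_c = 22,
                       humidity_pct = 45,
                       temp_noise_sd = 0.05,
                       humidity_noise_sd = 0.5,
                       rates_hz = c(body_temp = 4, env_temp = 1, humidity = 1,
                                    wrist_accel = 32, ankle_accel = 100,
                                    eda = 4, hr = 1),
                       walk_lap_s = 150,
                       run_lap_s = 90) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default eight-segment daily protocol
#' @return Tibble with columns `state`, `duration_s`.
#' @export
default_protocol <- function() {
  tibble::tibble(
    state = c("walk", "run_walk", "rest", "exercise", "rest", "exercise",
              "walk", "walk"),
    duration_s = c(600, 1200, 600, 900, 300, 900, 600, 600)
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$days < 1 || cfg$days != round(cfg$days)) {
    abort("days must be a positive integer")
  }
  pos <- c(cfg$hr_tau, cfg$eda_tau, cfg$rates_hz, cfg$walk_lap_s, cfg$run_lap_s,
           cfg$burst_s)
  if (any(pos <= 0)) abort("durations, rates and time constants must be positive")
  if (any(c(cfg$hr_noise_sd, cfg$accel_noise_sd, cfg$eda_noise_sd,
            cfg$temp_noise_sd, cfg$humidity_noise_sd) < 0)) {
    abort("noise sds must be non-negative")
  }
  if (!is.null(cfg$transition)) {
    if (is.null(cfg$dwell_mean_s)) abort("semi-Markov schedule needs dwell_mean_s")
    if (any(abs(rowSums(cfg$transition) - 1) > 1e-8)) {
      abort("transition matrix rows must sum to 1")
    }
    if (any(cfg$dwell_mean_s <= 0)) abort("dwell times must be positive")
  } else {
    if (any(cfg$protocol$duration_s <= 0)) abort("protocol durations must be positive")
    if (!all(cfg$protocol$state %in% c("rest", "walk", "run", "exercise", "run_walk"))) {
      abort("unknown protocol state")
    }
  }
  invisible(cfg)
}

# expand the schedule of one day into atomic (state, segment, t0, t1) rows
day_timeline <- function(cfg, offset) {
  if (!is.null(cfg$transition)) {
    states <- rownames(cfg$transition) %||% c("rest", "walk", "run", "exercise")
    total <- sum(cfg$dwell_mean_s) * 20  # target day length for the chain
    segs <- list(); t <- 0; seg <- 1L
    s <- sample.int(length(states), 1L)
    while (t < total) {
      dwell <- stats::rexp(1, rate = 1 / cfg$dwell_mean_s[states[s]])
      dwell <- max(dwell, 1)
      segs[[seg]] <- tibble::tibble(state = states[s], segment = seg,
                                    t0 = t, t1 = min(t + dwell, total))
      t <- t + dwell; seg <- seg + 1L
      s <- sample.int(length(states), 1L, prob = cfg$transition[s, ])
    }
    tl <- dplyr::bind_rows(segs)
  } else {
    rows <- list(); seg_id <- 0L
    for (i in seq_len(nrow(cfg$protocol))) {
      seg_id <- seg_id + 1L
      st <- cfg$protocol$state[i]; dur <- cfg$protocol$duration_s[i]
      if (st == "run_walk") {
        # alternate walk/run laps inside the block, keeping one segment id
        t <- 0; lap <- 0L; sub <- list()
        while (t < dur) {
          lap_state <- if (lap %% 2L == 0L) "walk" else "run"
          lap_len <- if (lap_state == "walk") cfg$walk_lap_s else cfg$run_lap_s
          sub[[lap + 1L]] <- tibble::tibble(state = lap_state, segment = seg_id,
                                            t0 = t, t1 = min(t + lap_len, dur))
          t <- t + lap_len; lap <- lap + 1L
        }
        sub <- dplyr::bind_rows(sub)
        sub$t0 <- sub$t0 + sum(head(cfg$protocol$duration_s, i - 1))
        sub$t1 <- sub$t1 + sum(head(cfg$protocol$duration_s, i - 1))
        rows[[i]] <- sub
      } else {
        t0 <- sum(head(cfg$protocol$duration_s, i - 1))
        rows[[i]] <- tibble::tibble(state = st, segment = seg_id,
                                    t0 = t0, t1 = t0 + dur)
      }
    }
    tl <- dplyr::bind_rows(rows)
  }
  tl$t0 <- tl$t0 + offset
  tl$t1 <- tl$t1 + offset
  tl
}

state_at <- function(timeline, t) {
  idx <- findInterval(t, timeline$t0)
  idx[idx < 1] <- 1L
  timeline$state[idx]
}

segment_at <- function(timeline, t) {
  idx <- findInterval(t, timeline$t0)
  idx[idx < 1] <- 1L
  timeline$segment[idx]
}

#' Simulate a multimodal wearable recording
#'
#' Generates one stream per modality at its configured rate plus a
#' ground-truth activity-label stream. Heart rate follows first-order
#' relaxation towards the current state's setpoint,
#' `dHR/dt = (setpoint - HR) / tau`, observed with Gaussian noise.
#' Identical `(config, seed)` give bit-identical output; each day is an
#' independent realization with its own seed offset.
#'
#' @param config a [sim_config()].
#' @param seed integer random seed.
#' @return A [wear_recording()] with a `labels` tibble
#'   (`timestamp_s`, `state`, `segment`).
#' @export
simulate_recording <- function(config, seed = 1) {
  validate_sim_config(config)
  cfg <- config
  day_list <- vector("list", cfg$days)
  offset <- 0
  for (d in seq_len(cfg$days)) {
    set.seed(seed + d - 1L)
    tl <- day_timeline(cfg, offset)
    duration <- max(tl$t1) - offset
    day_list[[d]] <- sim_one_day(cfg, tl, offset, duration)
    day_list[[d]]$days <- tibble::tibble(day = d, t_start = offset,
                                         t_end = offset + duration)
    offset <- offset + duration
  }
  streams <- purrr::map(names(day_list[[1]]$streams), function(nm) {
    dplyr::bind_rows(purrr::map(day_list, ~ .x$streams[[nm]]))
  })
  names(streams) <- names(day_list[[1]]$streams)
  labels <- dplyr::bind_rows(purrr::map(day_list, "labels"))
  meta <- tibble::tibble(
    sensor = names(cfg$rates_hz),
    rate_hz = as.numeric(cfg$rates_hz),
    channels = list("temp_c", "temp_c", "rh", c("ax", "ay", "az"),
                    c("ax", "ay", "az"), "eda_us", "hr_bpm")
  )
  wear_recording(streams, meta, dplyr::bind_rows(purrr::map(day_list, "days")),
                 target = "hr", context = "ankle_accel", labels = labels)
}

sim_accel <- function(cfg, tl, offset, duration, rate, amp_scale) {
  ts <- offset + seq(0, duration - 1 / rate, by = 1 / rate)
  st <- state_at(tl, ts)
  amp <- unname(cfg$accel_amp[st]) * amp_scale
  # slow per-sensor intensity modulation, shared by the three axes
  block <- floor((ts - offset) / cfg$jitter_block_s) + 1L
  jit <- exp(rnorm(max(block), 0, cfg$amp_jitter_sd))
  amp <- amp * jit[block]
  freq <- unname(cfg$accel_freq[st])
  # exercise: random-phase bursts alternating two frequencies
  ex <- st == "exercise"
  if (any(ex)) {
    burst_idx <- floor((ts - offset) / cfg$burst_s)
    freq[ex] <- ifelse(burst_idx[ex] %% 2 == 0, cfg$accel_freq[["exercise"]],
                       cfg$exercise_freq2)
  }
  out <- tibble::tibble(timestamp_s = ts)
  # one random phase per sensor; fixed axis offsets so the between-axis
  # phase relations (hence the covariance features) reflect the movement,
  # not the realization
  phase0 <- runif(1, 0, 2 * pi)
  axis_offset <- c(ax = 0, ay = 2.1, az = 4.2)
  for (ax in c("ax", "ay", "az")) {
    out[[ax]] <- amp * sin(2 * pi * freq * (ts - offset) + phase0 +
                             axis_offset[[ax]]) +
      rnorm(length(ts), 0, cfg$accel_noise_sd)
  }
  out
}

sim_one_day <- function(cfg, tl, offset, duration) {
  streams <- list()
  # near-constant environment / body channels
  for (nm in c("body_temp", "env_temp", "humidity")) {
    rate <- cfg$rates_hz[[nm]]
    ts <- offset + seq(0, duration - 1 / rate, by = 1 / rate)
    mu <- switch(nm, body_temp = cfg$body_temp_c, env_temp = cfg$env_temp_c,
                 humidity = cfg$humidity_pct)
    sdv <- if (nm == "humidity") cfg$humidity_noise_sd else cfg$temp_noise_sd
    col <- switch(nm, humidity = "rh", "temp_c")
    streams[[nm]] <- tibble::tibble(timestamp_s = ts)
    streams[[nm]][[col]] <- mu + rnorm(length(ts), 0, sdv)
  }
  streams$wrist_accel <- sim_accel(cfg, tl, offset, duration,
                                   cfg$rates_hz[["wrist_accel"]], cfg$wrist_scale)
  streams$ankle_accel <- sim_accel(cfg, tl, offset, duration,
                                   cfg$rates_hz[["ankle_accel"]], 1)
  # EDA: first-order response to per-state arousal level + tonic drift
  rate <- cfg$rates_hz[["eda"]]
  ts <- offset + seq(0, duration - 1 / rate, by = 1 / rate)
  st <- state_at(tl, ts)
  lvl <- numeric(length(ts))
  target <- cfg$eda_baseline + unname(cfg$eda_gain[st])
  lvl[1] <- target[1]
  decay <- exp(-(1 / rate) / cfg$eda_tau)
  for (i in seq_along(ts)[-1]) {
    lvl[i] <- target[i] + (lvl[i - 1] - target[i]) * decay
  }
  streams$eda <- tibble::tibble(
    timestamp_s = ts,
    eda_us = lvl + cfg$eda_drift * (ts - offset) + rnorm(length(ts), 0, cfg$eda_noise_sd)
  )
  # HR: exact discretization of first-order relaxation + observation noise
  rate <- cfg$rates_hz[["hr"]]
  ts <- offset + seq(0, duration - 1 / rate, by = 1 / rate)
  st <- state_at(tl, ts)
  sp <- unname(cfg$hr_setpoint[st])
  hr <- numeric(length(ts))
  hr[1] <- cfg$hr_init %||% sp[1]
  decay <- exp(-(1 / rate) / cfg$hr_tau)
  for (i in seq_along(ts)[-1]) {
    hr[i] <- sp[i] + (hr[i - 1] - sp[i]) * decay
  }
  streams$hr <- tibble::tibble(
    timestamp_s = ts,
    hr_bpm = hr + rnorm(length(ts), 0, cfg$hr_noise_sd)
  )
  lab_ts <- offset + seq(0, duration - 1, by = 1)
  labels <- tibble::tibble(timestamp_s = lab_ts,
                           state = state_at(tl, lab_ts),
                           segment = segment_at(tl, lab_ts))
  list(streams = streams, labels = labels)
}

#' Planted sparse linear response model
#'
#' Describes a ground-truth sensor support used to overwrite a recording's
#' heart-rate stream with a known sparse linear signal, for support-recovery
#' testing. Coefficients for ordinary sensor groups apply to that group's
#' standardized window features; the heart-rate group enters
#' autoregressively through `hr_ar`, the coefficient on the response lagged
#' by the history horizon, so the regenerated response remains consistent
#' with the history features later rebuilt from it.
#'
#' @param groups named list of numeric coefficient vectors (standardized
#'   units), one per planted sensor group; each vector must match the
#'   group's feature count (1 for temperatures/humidity, 21 for
#'   accelerometers, 6 for EDA). Groups absent from the list have
#'   exactly-zero coefficients.
#' @param hr_ar autoregressive coefficient on the lagged response
#'   (|hr_ar| < 1); 0 leaves the heart-rate group out of the support.
#' @param intercept response intercept (bpm).
#' @param noise_sd Gaussian noise sd (bpm); alternatively give `snr`.
#' @param snr signal-to-noise ratio (variance ratio); used when `noise_sd`
#'   is NULL.
#' @return An object of class `planted_model`.
#' @export
planted_model <- function(groups, hr_ar = 0, intercept = 80,
                          noise_sd = NULL, snr = NULL) {
  if (abs(hr_ar) >= 1) abort("hr_ar must have magnitude below 1")
  if (is.null(noise_sd) && is.null(snr)) noise_sd <- 0
  structure(list(groups = groups, hr_ar = hr_ar, intercept = intercept,
                 noise_sd = noise_sd, snr = snr),
            class = "planted_model")
}

#' Replace a recording's heart-rate stream with a planted linear response
#'
#' Builds the grouped window features of the recording, standardizes them
#' over all rows, and regenerates the target stream as
#' `intercept + sum_k Z_k beta_k (+ hr_ar * lagged response) + noise`.
#' The true support is recorded in attributes for later recovery checks.
#'
#' @param rec a [wear_recording()].
#' @param model a [planted_model()].
#' @param seed integer seed for the noise.
#' @param window,dh feature window length and history horizon (s) the
#'   downstream design is expected to use.
#' @return The modified [wear_recording()], with attributes `true_support`
#'   (character), `planted` (the model) and `noise_sd` (realized value).
#' @export
plant_linear_response <- function(rec, model, seed = 1, window = 5, dh = 30) {
  design <- build_design(rec, dh = Inf, window = window, stride = 1)
  groups <- attr(design, "groups")
  bad <- setdiff(names(model$groups), names(groups))
  if (length(bad)) {
    abort(paste0("planted groups not present in recording: ",
                 paste(bad, collapse = ", ")))
  }
  signal <- rep(0, nrow(design))
  for (g in names(model$groups)) {
    cols <- groups[[g]]
    beta <- model$groups[[g]]
    if (length(beta) != length(cols)) {
      abort(paste0("group '", g, "' expects ", length(cols), " coefficients"))
    }
    Z <- as.matrix(design[cols])
    Z <- scale(Z)
    Z[, attr(Z, "scaled:scale") < 1e-12] <- 0
    signal <- signal + as.numeric(Z %*% beta)
  }
  t_row <- design$t
  gen_y <- function(noise) {
    y <- numeric(length(t_row))
    for (i in seq_along(t_row)) {
      ar <- 0
      if (model$hr_ar != 0 && is.finite(dh)) {
        j <- match(t_row[i] - dh, t_row)
        ar <- if (!is.na(j)) model$hr_ar * (y[j] - model$intercept) else 0
      }
      y[i] <- model$intercept + signal[i] + ar + noise[i]
    }
    y
  }
  y0 <- gen_y(rep(0, length(t_row)))
  noise_sd <- model$noise_sd %||% (sd(y0) / sqrt(model$snr))
  set.seed(seed)
  y <- gen_y(rnorm(length(t_row), 0, noise_sd))
  # grid value at t is the raw 1 Hz sample at t - 1
  hr <- rec$streams[[rec$target]]
  new_val <- y[match(hr$timestamp_s + 1, t_row)]
  new_val[is.na(new_val)] <- model$intercept
  hr[[2]] <- new_val
  rec$streams[[rec$target]] <- hr
  support <- names(model$groups)[purrr::map_lgl(model$groups, ~ any(.x != 0))]
  if (model$hr_ar != 0) support <- c(support, "hr")
  attr(rec, "true_support") <- support
  attr(rec, "planted") <- model
  attr(rec, "noise_sd") <- noise_sd
  rec
}
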