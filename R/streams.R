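#' Multimodal wearable recordings
#'
#' A recording bundles one timestamped stream per sensor modality (ambient
#' temperature, humidity, skin temperature, wrist and ankle 3-axis
#' acceleration, electrodermal activity) together with the target heart-rate
#' stream, partitioned into recording days. Streams are plain tibbles with a
#' `timestamp_s` column (seconds, 0 at recording start) followed by one
#' column per channel; per-stream metadata (sampling rate, channel names)
#' lives in the `meta` tibble.
#'
#' @param streams named list of tibbles, each with a strictly increasing
#'   `timestamp_s` column followed by channel columns.
#' @param meta tibble with columns `sensor`, `rate_hz` and list-column
#'   `channels`; one row per stream.
#' @param days tibble with columns `day`, `t_start`, `t_end` giving the
#'   half-open time span `[t_start, t_end)` of each recording day.
#' @param target name of the target stream (single-channel heart rate, bpm).
#' @param context character vector of sensor names used for activity
#'   recognition (defaults to the ankle accelerometer).
#' @param labels optional tibble of ground-truth activity labels
#'   (`timestamp_s`, `state`, `segment`); emitted by the simulator for
#'   testing only, never read by the analysis pipeline.
#'
#' @return An object of class `wear_recording`.
#' @export
wear_recording <- function(streams, meta, days, target = "hr",
                           context = "ankle_accel", labels = NULL) {
  rec <- structure(
    list(streams = streams, meta = meta, days = days,
         target = target, context = context, labels = labels),
    class = "wear_recording"
  )
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (!rec$target %in% names(rec$streams)) {
    abort(paste0("recording has no target stream '", rec$target, "'"))
  }
  if (ncol(rec$streams[[rec$target]]) != 2L) {
    abort("target stream must have exactly one channel")
  }
  bad_ctx <- setdiff(rec$context, names(rec$streams))
  if (length(bad_ctx)) {
    abort(paste0("context sensors not present: ", paste(bad_ctx, collapse = ", ")))
  }
  for (nm in names(rec$streams)) {
    ts <- rec$streams[[nm]]$timestamp_s
    if (length(ts) == 0L) abort(paste0("stream '", nm, "' is empty"))
    d <- diff(ts)
    if (any(d <= 0)) {
      abort(paste0("stream '", nm, "' has non-increasing timestamps at row ",
                   which(d <= 0)[1] + 1L))
    }
  }
  # every stream must cover every day (allowing one sample period of slack)
  for (i in seq_len(nrow(rec$days))) {
    t0 <- rec$days$t_start[i]; t1 <- rec$days$t_end[i]
    for (nm in names(rec$streams)) {
      ts <- rec$streams[[nm]]$timestamp_s
      rate <- rec$meta$rate_hz[rec$meta$sensor == nm]
      if (min(ts) > t0 + 1 / rate || max(ts) < t1 - 2 / rate) {
        abort(paste0("stream '", nm, "' does not cover day ", rec$days$day[i]))
      }
    }
  }
  invisible(rec)
}

#' @export
print.wear_recording <- function(x, ...) {
  dur <- sum(x$days$t_end - x$days$t_start)
  cat("<wear_recording> ", nrow(x$days), " day(s), ", dur, " s total\n", sep = "")
  cat("  target: ", x$target, "; context: ",
      paste(x$context, collapse = ", "), "\n", sep = "")
  info <- purrr::map_chr(names(x$streams), function(nm) {
    paste0(nm, " (", x$meta$rate_hz[x$meta$sensor == nm], " Hz, ",
           nrow(x$streams[[nm]]), " samples)")
  })
  cat("  streams: ", paste(info, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Day index of each timestamp
#'
#' @param rec a [wear_recording()].
#' @param timestamp_s numeric vector of times (s).
#' @return Integer day indices (NA outside all days).
#' @export
day_of <- function(rec, timestamp_s) {
  idx <- rep(NA_integer_, length(timestamp_s))
  for (i in seq_len(nrow(rec$days))) {
    in_day <- timestamp_s >= rec$days$t_start[i] & timestamp_s < rec$days$t_end[i]
    idx[in_day] <- rec$days$day[i]
  }
  idx
}

#' Write a recording to CSV files plus a JSON manifest
#'
#' One CSV per modality (`timestamp_s` first column, then channels), a
#' `labels.csv` when ground-truth labels are present, and a `manifest.json`
#' listing files, sampling rates and day boundaries.
#'
#' @param rec a [wear_recording()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (nm in names(rec$streams)) {
    f <- paste0(nm, ".csv")
    readr::write_csv(rec$streams[[nm]], file.path(dir, f))
    files[[nm]] <- list(
      file = f,
      rate_hz = rec$meta$rate_hz[rec$meta$sensor == nm],
      channels = as.list(setdiff(names(rec$streams[[nm]]), "timestamp_s"))
    )
  }
  if (!is.null(rec$labels)) {
    readr::write_csv(rec$labels, file.path(dir, "labels.csv"))
  }
  manifest <- list(
    format = "wearsel-recording-v1",
    target = rec$target,
    context = as.list(rec$context),
    streams = files,
    days = purrr::pmap(rec$days, function(day, t_start, t_end) {
      list(day = day, t_start = t_start, t_end = t_end)
    }),
    labels = if (!is.null(rec$labels)) "labels.csv"
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Validates monotone timestamps and that each stream's empirical rate
#' (median timestamp spacing) is within 1% of its declared rate.
#'
#' @param manifest path to a `manifest.json`.
#' @return A [wear_recording()].
#' @export
read_recording <- function(manifest) {
  if (!file.exists(manifest)) abort(paste0("manifest not found: ", manifest))
  m <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  if (is.null(m$streams[[m$target]])) {
    abort(paste0("manifest is missing the target stream '", m$target, "'"))
  }
  streams <- list(); meta_rows <- list()
  for (nm in names(m$streams)) {
    s <- m$streams[[nm]]
    f <- file.path(dir, s$file)
    if (!file.exists(f)) abort(paste0("stream file missing for '", nm, "': ", f))
    dat <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    if (names(dat)[1] != "timestamp_s") {
      abort(paste0("stream '", nm, "': first column must be timestamp_s"))
    }
    d <- diff(dat$timestamp_s)
    if (any(d <= 0)) {
      abort(paste0("stream '", nm, "': non-monotone timestamp at row ",
                   which(d <= 0)[1] + 1L))
    }
    emp_rate <- 1 / median(d)
    if (abs(emp_rate - s$rate_hz) / s$rate_hz > 0.01) {
      abort(paste0("stream '", nm, "': empirical rate ", signif(emp_rate, 5),
                   " Hz differs from declared ", s$rate_hz, " Hz by more than 1%"))
    }
    streams[[nm]] <- dat
    meta_rows[[nm]] <- tibble::tibble(sensor = nm, rate_hz = as.numeric(s$rate_hz),
                                      channels = list(unlist(s$channels)))
  }
  days <- dplyr::bind_rows(purrr::map(m$days, tibble::as_tibble))
  labels <- NULL
  if (!is.null(m$labels) && file.exists(file.path(dir, m$labels))) {
    labels <- readr::read_csv(file.path(dir, m$labels),
                              show_col_types = FALSE, progress = FALSE)
  }
  wear_recording(streams, dplyr::bind_rows(meta_rows), days,
                 target = m$target, context = unlist(m$context), labels = labels)
}

#' Resample every stream onto a common analysis grid
#'
#' The grid for each day is `t_start + 1/rate, ..., t_end` (half-open
#' windows `[t - 1/rate, t)`). Channels sampled at or above the grid rate
#' are window-averaged; channels below the grid rate are linearly
#' interpolated at the grid times. The default 1 Hz grid matches the native
#' heart-rate sampling.
#'
#' @param rec a [wear_recording()].
#' @param grid_hz grid rate in Hz.
#' @return A [wear_recording()] whose streams all share the grid.
#' @export
align_to_grid <- function(rec, grid_hz = 1) {
  dt <- 1 / grid_hz
  grids <- purrr::pmap(rec$days, function(day, t_start, t_end) {
    seq(t_start + dt, t_end, by = dt)
  })
  grid <- unlist(grids)
  if (length(grid) == 0L) abort("empty time overlap between streams")
  streams <- purrr::imap(rec$streams, function(s, nm) {
    rate <- rec$meta$rate_hz[rec$meta$sensor == nm]
    chans <- setdiff(names(s), "timestamp_s")
    out <- tibble::tibble(timestamp_s = grid)
    for (ch in chans) {
      if (rate >= grid_hz) {
        # mean over [t - dt, t): bin edges at grid - dt
        bin <- findInterval(s$timestamp_s, grid - dt)
        ok <- bin >= 1 & bin <= length(grid)
        v <- tapply(s[[ch]][ok], bin[ok], mean)
        col <- rep(NA_real_, length(grid))
        col[as.integer(names(v))] <- as.numeric(v)
        # fill any empty bins by interpolation from neighbours
        if (anyNA(col)) {
          col <- approx(grid[!is.na(col)], col[!is.na(col)], xout = grid,
                        rule = 2)$y
        }
        out[[ch]] <- col
      } else {
        out[[ch]] <- approx(s$timestamp_s, s[[ch]], xout = grid, rule = 2)$y
      }
    }
    out
  })
  meta <- rec$meta
  meta$rate_hz <- grid_hz
  wear_recording(streams, meta, rec$days, target = rec$target,
                 context = rec$context, labels = rec$labels)
}

#' Split a recording into one recording per day
#'
#' @param rec a [wear_recording()].
#' @return A list of single-day `wear_recording`s; [bind_days()] restores
#'   the original.
#' @export
split_days <- function(rec) {
  purrr::pmap(rec$days, function(day, t_start, t_end) {
    streams <- purrr::map(rec$streams, function(s) {
      dplyr::filter(s, .data$timestamp_s >= t_start, .data$timestamp_s < t_end)
    })
    labels <- NULL
    if (!is.null(rec$labels)) {
      labels <- dplyr::filter(rec$labels, .data$timestamp_s >= t_start,
                              .data$timestamp_s < t_end)
    }
    wear_recording(streams, rec$meta,
                   tibble::tibble(day = day, t_start = t_start, t_end = t_end),
                   target = rec$target, context = rec$context, labels = labels)
  })
}

#' Concatenate single-day recordings back into one recording
#'
#' @param recs list of `wear_recording`s with disjoint, ordered day spans.
#' @return A [wear_recording()].
#' @export
bind_days <- function(recs) {
  streams <- purrr::map(names(recs[[1]]$streams), function(nm) {
    dplyr::bind_rows(purrr::map(recs, ~ .x$streams[[nm]]))
  })
  names(streams) <- names(recs[[1]]$streams)
  labels <- NULL
  if (!is.null(recs[[1]]$labels)) {
    labels <- dplyr::bind_rows(purrr::map(recs, "labels"))
  }
  wear_recording(streams, recs[[1]]$meta,
                 dplyr::bind_rows(purrr::map(recs, "days")),
                 target = recs[[1]]$target, context = recs[[1]]$context,
                 labels = labels)
}
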