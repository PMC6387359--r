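#' Accelerometer window features
#'
#' Computes the 21 statistics of one 3-axis window: per axis the mean,
#' variance, skewness, excess kurtosis, peak periodogram magnitude and the
#' frequency of that peak (18 features), plus the three pairwise
#' covariances. The periodogram uses the mean-removed window with a
#' rectangular taper; the peak is searched over bins in (0, Nyquist].
#' Skewness and kurtosis of a zero-variance window are defined as 0, and a
#' constant window has peak magnitude 0 (reported at the lowest bin).
#'
#' @param window numeric matrix (samples x 3 axes).
#' @param rate_hz sampling rate of the window (Hz).
#' @return Named numeric vector of length 21, in the frozen order
#'   `{ax,ay,az} x {mean,var,skew,kurt,specmag,specfreq}` then
#'   `cov_xy, cov_xz, cov_yz`.
#' @export
accel_features <- function(window, rate_hz) {
  window <- as.matrix(window)
  n <- nrow(window)
  if (n < 8) abort("accelerometer window too short (need >= 8 samples)")
  out <- numeric(0)
  for (j in 1:3) {
    x <- window[, j]
    pk <- periodogram_peak(x, rate_hz)
    out <- c(out, mean(x), var(x), sample_skewness(x), sample_kurtosis(x),
             pk[1], pk[2])
  }
  out <- c(out, cov(window[, 1], window[, 2]), cov(window[, 1], window[, 3]),
           cov(window[, 2], window[, 3]))
  names(out) <- accel_feature_names()
  out
}

accel_feature_names <- function() {
  c(paste0(rep(c("ax", "ay", "az"), each = 6),
           "_", c("mean", "var", "skew", "kurt", "specmag", "specfreq")),
    "cov_xy", "cov_xz", "cov_yz")
}

sample_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 < 1e-12) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

sample_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 < 1e-12) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

periodogram_peak <- function(x, rate_hz) {
  n <- length(x)
  d <- x - mean(x)
  p <- Mod(fft(d))^2 / n
  nb <- floor(n / 2)
  bins <- 2:(nb + 1)          # frequencies (0, Nyquist]
  freqs <- (1:nb) * rate_hz / n
  i <- which.max(p[bins])
  c(p[bins][i], freqs[i])
}

#' Electrodermal activity window features
#'
#' Six statistics of a 1-d window: mean, linear trend (least-squares slope
#' against time, per second), variance, skewness, excess kurtosis, and
#' absolute range (max - min).
#'
#' @param values numeric vector of samples.
#' @param times sample times (s), same length as `values`.
#' @return Named numeric vector
#'   `(mean, trend, var, skew, kurt, range)`.
#' @export
eda_features <- function(values, times) {
  n <- length(values)
  if (n < 4) abort("EDA window too short (need >= 4 samples)")
  tc <- times - mean(times)
  stt <- sum(tc^2)
  trend <- if (stt < 1e-12) 0 else sum(tc * (values - mean(values))) / stt
  out <- c(mean(values), trend, var(values), sample_skewness(values),
           sample_kurtosis(values), max(values) - min(values))
  names(out) <- c("mean", "trend", "var", "skew", "kurt", "range")
  out
}

#' Heart-rate history features
#'
#' The response lagged by the history horizon plus its first and second
#' discrete differences on the 1 Hz analysis grid:
#' `(y(t - dh), y(t - dh) - y(t - dh - 1), y(t - dh) - 2 y(t - dh - 1) + y(t - dh - 2))`.
#'
#' @param y aligned response tibble (`timestamp_s`, value) on the 1 Hz grid.
#' @param t row end-time (s).
#' @param dh history horizon (s); `Inf` is not valid here (the group is
#'   omitted from the design instead).
#' @return Named numeric vector `(lag, diff1, diff2)`.
#' @export
hr_history_features <- function(y, t, dh) {
  idx <- match(round(t - dh - 0:2), round(y$timestamp_s))
  if (anyNA(idx)) abort("insufficient heart-rate history for this row")
  v <- y[[2]][idx]
  c(lag = v[1], diff1 = v[1] - v[2], diff2 = v[1] - 2 * v[2] + v[3])
}

hr_feature_names <- function() c("lag", "diff1", "diff2")

#' Build the grouped sliding-window design matrix
#'
#' One row per stride step on the 1 Hz analysis grid where every feature
#' group is computable. The seven default groups are body temperature
#' (window mean, 1 feature), environmental temperature (1), humidity (1),
#' wrist acceleration (21), ankle acceleration (21), EDA (6) and heart-rate
#' history (3; omitted when `dh = Inf`), for p = 54 columns named
#' `<sensor>__<feature>`. The response is the aligned heart rate at the
#' row's end-time. Accelerometer and EDA windows reference the raw native-
#' rate samples in the half-open window `[t - window, t)`; rows whose
#' heart-rate history would reach before the recording start are dropped,
#' not imputed.
#'
#' @param rec a [wear_recording()].
#' @param dh history horizon (s), a positive number or `Inf`.
#' @param window window length (s).
#' @param stride stride between rows (s).
#' @return A tibble of class `wear_design` with columns `t`, `day`,
#'   `cluster` (NA until assigned), `y`, then the feature columns; the
#'   group partition is in `attr(, "groups")`.
#' @export
build_design <- function(rec, dh = 30, window = 5, stride = 1) {
  if (window <= 0 || stride <= 0) abort("window and stride must be positive")
  if (!isTRUE(dh > 0)) abort("dh must be positive or Inf")
  head_s <- window + if (is.finite(dh)) dh + 2 else 0
  y_grid <- align_stream_1hz(rec, rec$target)
  rows <- list()
  for (i in seq_len(nrow(rec$days))) {
    t0 <- rec$days$t_start[i]; t1 <- rec$days$t_end[i]
    if (t1 - t0 < head_s + 1) {
      abort(paste0("day ", rec$days$day[i], " shorter than window + history (",
                   head_s, " s)"))
    }
    t <- seq(t0 + head_s, t1, by = stride)
    rows[[i]] <- tibble::tibble(t = t, day = rec$days$day[i])
  }
  rows <- dplyr::bind_rows(rows)
  t <- rows$t
  feats <- list()
  for (nm in c("body_temp", "env_temp", "humidity")) {
    s <- rec$streams[[nm]]
    feats[[paste0(nm, "__mean")]] <- window_means(s$timestamp_s, s[[2]], t, window)
  }
  for (nm in c("wrist_accel", "ankle_accel")) {
    s <- rec$streams[[nm]]
    rate <- rec$meta$rate_hz[rec$meta$sensor == nm]
    M <- window_apply(s$timestamp_s, as.matrix(s[c("ax", "ay", "az")]), t, window,
                      function(w) accel_features(w, rate), 21L)
    colnames(M) <- paste0(nm, "__", accel_feature_names())
    for (cn in colnames(M)) feats[[cn]] <- M[, cn]
  }
  s <- rec$streams$eda
  M <- window_apply(s$timestamp_s, cbind(s$eda_us, s$timestamp_s), t, window,
                    function(w) eda_features(w[, 1], w[, 2]), 6L)
  colnames(M) <- paste0("eda__", c("mean", "trend", "var", "skew", "kurt", "range"))
  for (cn in colnames(M)) feats[[cn]] <- M[, cn]
  groups <- list(
    body_temp = "body_temp__mean", env_temp = "env_temp__mean",
    humidity = "humidity__mean",
    wrist_accel = paste0("wrist_accel__", accel_feature_names()),
    ankle_accel = paste0("ankle_accel__", accel_feature_names()),
    eda = colnames(M)
  )
  if (is.finite(dh)) {
    yi <- match(round(t - dh), round(y_grid$timestamp_s))
    y1 <- match(round(t - dh - 1), round(y_grid$timestamp_s))
    y2 <- match(round(t - dh - 2), round(y_grid$timestamp_s))
    if (anyNA(c(yi, y1, y2))) abort("insufficient heart-rate history")
    v0 <- y_grid$value[yi]; v1 <- y_grid$value[y1]; v2 <- y_grid$value[y2]
    feats[["hr__lag"]] <- v0
    feats[["hr__diff1"]] <- v0 - v1
    feats[["hr__diff2"]] <- v0 - 2 * v1 + v2
    groups$hr <- c("hr__lag", "hr__diff1", "hr__diff2")
  }
  y <- y_grid$value[match(round(t), round(y_grid$timestamp_s))]
  design <- tibble::tibble(t = t, day = rows$day, cluster = NA_integer_, y = y)
  design <- dplyr::bind_cols(design, tibble::as_tibble(feats))
  structure(design, groups = groups, window = window, dh = dh, stride = stride,
            class = c("wear_design", class(design)))
}

# aligned 1 Hz series of one stream: grid value at t = mean of raw samples
# in [t - 1, t)
align_stream_1hz <- function(rec, sensor) {
  s <- rec$streams[[sensor]]
  grid <- unlist(purrr::pmap(rec$days, function(day, t_start, t_end) {
    seq(t_start + 1, t_end, by = 1)
  }))
  bin <- findInterval(s$timestamp_s, grid - 1)
  ok <- bin >= 1 & bin <= length(grid)
  v <- tapply(s[[2]][ok], bin[ok], mean)
  val <- rep(NA_real_, length(grid))
  val[as.integer(names(v))] <- as.numeric(v)
  if (anyNA(val)) {
    val <- approx(grid[!is.na(val)], val[!is.na(val)], xout = grid, rule = 2)$y
  }
  tibble::tibble(timestamp_s = grid, value = val)
}

window_means <- function(ts, values, t_end, window) {
  i0 <- findInterval(t_end - window, ts, left.open = TRUE) + 1L
  i1 <- findInterval(t_end, ts, left.open = TRUE)
  cs <- c(0, cumsum(values))
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

window_apply <- function(ts, values, t_end, window, f, nf) {
  i0 <- findInterval(t_end - window, ts, left.open = TRUE) + 1L
  i1 <- findInterval(t_end, ts, left.open = TRUE)
  out <- matrix(NA_real_, nrow = length(t_end), ncol = nf)
  for (r in seq_along(t_end)) {
    out[r, ] <- f(values[i0[r]:i1[r], , drop = FALSE])
  }
  out
}

#' Standardize a design matrix over a set of training rows
#'
#' Centers and scales every feature column and the response to mean 0 and
#' sd 1 on the training rows. Columns with (near) zero variance on the
#' training rows -- typically near-constant humidity or temperature
#' channels -- are flagged; group-lasso fitting drops them with a warning.
#'
#' @param design a [build_design()] result.
#' @param rows integer row indices to compute the parameters on (default:
#'   all rows).
#' @return A list with the standardized matrix `Z`, response `y`, the
#'   group partition restricted to kept columns, and the parameters
#'   (`center`, `scale`, `y_center`, `y_scale`, `dropped`).
#' @export
standardize_design <- function(design, rows = seq_len(nrow(design))) {
  groups <- attr(design, "groups")
  cols <- unlist(groups, use.names = FALSE)
  X <- as.matrix(design[rows, cols])
  center <- colMeans(X)
  scl <- apply(X, 2, sd)
  dropped <- cols[scl < 1e-10]
  keep <- setdiff(cols, dropped)
  Z <- sweep(sweep(as.matrix(design[rows, keep]), 2, center[keep]), 2,
             scl[keep], "/")
  y_center <- mean(design$y[rows])
  y_scale <- sd(design$y[rows])
  if (y_scale < 1e-10) abort("response has zero variance on training rows")
  kept_groups <- purrr::map(groups, ~ intersect(.x, keep))
  kept_groups <- kept_groups[purrr::map_int(kept_groups, length) > 0]
  list(Z = Z, y = (design$y[rows] - y_center) / y_scale,
       groups = kept_groups, center = center[keep], scale = scl[keep],
       y_center = y_center, y_scale = y_scale, dropped = dropped)
}

#' Persist a design matrix as CSV plus JSON sidecar
#'
#' @param design a [build_design()] result.
#' @param path CSV output path; the sidecar is written next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_csv(tibble::as_tibble(design), path)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(groups = attr(design, "groups"), window = attr(design, "window"),
         dh = attr(design, "dh"), stride = attr(design, "stride")),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
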