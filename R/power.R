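#' Per-sensor current-draw table
#'
#' Maps each sensor to the incremental current (mA) it adds to the system
#' when active, together with the full-system baseline current `i_total`.
#' Two tables ship with the package:
#'
#' * `"default"` -- per-sensor increments reconstructed from the device's
#'   published per-configuration reduction accounting by solving the linear
#'   system its cells form (each reduction is the sum of the disabled
#'   sensors' increments), under the symmetry assumption that the
#'   environmental-temperature and humidity sensors draw equal current.
#'   The baseline current is pinned by the published percentage values.
#' * `"measured"` -- raw bench measurements of the prototype wristband and
#'   chest patch (wrist full function 4.13 mA, chest 5.89 mA), with the
#'   ankle accelerometer assigned the chest-accelerometer increment and
#'   skin temperature / EDA assigned the wrist-accelerometer increment.
#'   The two tables disagree; the reconstructed one is the default because
#'   it is self-consistent with the reduction accounting.
#'
#' @param source `"default"`, `"measured"`, or a path to a JSON file with
#'   fields `sensors` (name -> mA) and `i_total_mA`.
#' @return A tibble of class `power_table` with columns `sensor`,
#'   `current_ma` and attribute `i_total`.
#' @export
power_table <- function(source = "default") {
  path <- switch(source,
    default = system.file("extdata", "power_table.json", package = "wearsel"),
    measured = system.file("extdata", "power_table_measured.json",
                           package = "wearsel"),
    source)
  if (!file.exists(path)) abort(paste0("power table not found: ", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- tibble::tibble(sensor = names(j$sensors),
                        current_ma = as.numeric(unlist(j$sensors)))
  if (any(tab$current_ma < 0)) abort("negative current in power table")
  if (sum(tab$current_ma) > j$i_total_mA + 1e-9) {
    abort("sensor increments exceed the total system current")
  }
  structure(tab, i_total = j$i_total_mA,
            class = c("power_table", class(tab)))
}

#' Current reduction from duty-cycling the inactive sensors
#'
#' The reduction is the sum of the incremental currents of the sensors NOT
#' in the active set, i.e. the sensors the cluster's model does not use and
#' which can be placed in idle mode.
#'
#' @param active character vector of active sensor names.
#' @param power a [power_table()].
#' @return Tibble with one row: `delta_ma`, `delta_pct`
#'   (100 * delta / i_total).
#' @export
current_reduction <- function(active, power) {
  unknown <- setdiff(active, power$sensor)
  if (length(unknown)) {
    abort(paste0("unknown sensor(s): ", paste(unknown, collapse = ", ")))
  }
  inactive <- setdiff(power$sensor, active)
  delta <- sum(power$current_ma[power$sensor %in% inactive])
  tibble::tibble(delta_ma = delta,
                 delta_pct = 100 * delta / attr(power, "i_total"))
}

#' Cluster-size-weighted average current reduction
#'
#' `I_avg = sum_i(N_ci * I_ci) / sum_i(N_ci)` over clusters.
#'
#' @param delta per-cluster reductions (mA or %).
#' @param n per-cluster sizes `N_ci` (> 0).
#' @return The weighted mean.
#' @export
average_reduction <- function(delta, n) {
  if (length(delta) != length(n)) abort("delta and n must have equal length")
  if (any(n <= 0)) abort("cluster sizes must be positive")
  sum(n * delta) / sum(n)
}

#' Sensor dropout levels along a regularization path
#'
#' For each sensor group, the largest penalty at which it is still active
#' (0 if never active). Sensors whose level falls below the CV-selected
#' penalty are the ones duty-cycled off at the operating point.
#'
#' @param path a [lambda_path()].
#' @return Tibble `sensor`, `lambda_level`.
#' @export
dropout_levels <- function(path) {
  groups <- names(attr(path, "std")$groups)
  purrr::map_dfr(groups, function(g) {
    on <- purrr::map_lgl(path$active, ~ g %in% .x)
    tibble::tibble(sensor = g,
                   lambda_level = if (any(on)) max(path$lambda[on]) else 0)
  })
}

#' Per-cluster power report
#'
#' @param active_sets named list (by cluster) of active sensor sets.
#' @param n_ci cluster sizes (same order).
#' @param power a [power_table()].
#' @return Tibble of class `power_report`: one row per cluster
#'   (`cluster`, `n`, `delta_ma`, `delta_pct`, `active` list-column) with
#'   the size-weighted average in `attr(, "average")`.
#' @export
power_report <- function(active_sets, n_ci, power) {
  if (length(active_sets) != length(n_ci)) {
    abort("one size per cluster is required")
  }
  rows <- purrr::imap_dfr(active_sets, function(act, cl) {
    red <- current_reduction(act, power)
    tibble::tibble(cluster = cl, delta_ma = red$delta_ma,
                   delta_pct = red$delta_pct, active = list(act))
  })
  rows$n <- as.numeric(n_ci)
  avg <- tibble::tibble(
    delta_ma = average_reduction(rows$delta_ma, rows$n),
    delta_pct = average_reduction(rows$delta_pct, rows$n))
  structure(rows[, c("cluster", "n", "delta_ma", "delta_pct", "active")],
            average = avg, class = c("power_report", class(rows)))
}

#' Accuracy-power trade-off along a path
#'
#' For penalties at and above the selected one, pairs the increase in
#' held-out RMSE over the optimum with the percent current reduction of
#' that penalty's active sensor set. With nested active sets the reduction
#' is non-decreasing as the penalty grows.
#'
#' @param path a [lambda_path()] carrying a held-out RMSE column (see
#'   [path_rmse()]).
#' @param lambda_opt the selected penalty.
#' @param power a [power_table()].
#' @param rmse_col name of the RMSE column.
#' @return Tibble of class `tradeoff_curve`: `lambda`, `rmse_increase`,
#'   `delta_pct`, `n_active`, ordered from the optimum towards larger
#'   penalties.
#' @export
tradeoff_curve <- function(path, lambda_opt, power, rmse_col = "test_rmse") {
  if (!rmse_col %in% names(path)) abort("path has no held-out RMSE column")
  keep <- which(path$lambda >= lambda_opt - 1e-12)
  keep <- keep[order(path$lambda[keep])]        # from lambda_opt upward
  rmse0 <- path[[rmse_col]][which.min(abs(path$lambda - lambda_opt))]
  out <- purrr::map_dfr(keep, function(i) {
    red <- current_reduction(path$active[[i]], power)
    tibble::tibble(lambda = path$lambda[i],
                   rmse_increase = path[[rmse_col]][i] - rmse0,
                   delta_pct = red$delta_pct,
                   n_active = path$n_active[i])
  })
  structure(out, class = c("tradeoff_curve", class(out)))
}
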