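#' Prediction-accuracy metrics
#'
#' Mean absolute error, root mean square error, range-normalized RMSE
#' (`RMSE / (y_max - y_min)`) and the coefficient of determination
#' `R^2 = 1 - SSE / SST`.
#'
#' @param y observed response (bpm).
#' @param yhat predictions (bpm).
#' @return Tibble with columns `mae`, `rmse`, `nrmse`, `r_squared`, `n`,
#'   `y_mean`, `y_min`, `y_max`.
#' @export
hr_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("y and yhat must have equal length")
  if (length(y) < 2) abort("need at least 2 observations")
  rng <- max(y) - min(y)
  if (rng <= 0) abort("NRMSE undefined: response is constant")
  e <- yhat - y
  sse <- sum(e^2)
  sst <- sum((y - mean(y))^2)
  tibble::tibble(
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    nrmse = sqrt(mean(e^2)) / rng,
    r_squared = 1 - sse / sst,
    n = length(y), y_mean = mean(y), y_min = min(y), y_max = max(y))
}

#' Constant (persistence) predictor baseline
#'
#' Predicts the response at time `t` with its own value `dh` seconds
#' earlier, `yhat(t) = y(t - dh)`. With `dh = Inf` no history is available
#' and the training-mean predictor is returned instead (flagged via the
#' `"flat"` attribute).
#'
#' @param design a [build_design()] result (its `hr__lag` column is the
#'   response lagged by the design's horizon).
#' @param rows rows to predict.
#' @param train_mean training response mean, used when `dh = Inf`.
#' @return Numeric predictions (bpm).
#' @export
constant_predictor <- function(design, rows = seq_len(nrow(design)),
                               train_mean = NULL) {
  if (is.finite(attr(design, "dh"))) {
    return(design$hr__lag[rows])
  }
  if (is.null(train_mean)) abort("dh = Inf needs a training mean")
  structure(rep(train_mean, length(rows)), flat = TRUE)
}

#' Run the activity-aware prediction pipeline end to end
#'
#' Executes the full method on a multi-day recording: build the grouped
#' window design, fit the activity cluster model on the training days,
#' assign every row to a cluster, select the penalty per cluster by
#' day-wise cross-validation, evaluate on the held-out test day (clustered
#' and unclustered variants plus the persistence baseline), and derive the
#' power report and accuracy-power trade-off curves from the selected
#' sensor sets. Clusters with fewer than 30 test rows are flagged in the
#' per-cluster metrics. Fully seeded: identical inputs give identical
#' reports.
#'
#' @param rec a [wear_recording()] with at least 3 days (the last day is
#'   the test day, the others train).
#' @param dh history horizon (s) or `Inf`.
#' @param window,stride design window and stride (s).
#' @param K number of activity clusters.
#' @param scheme penalty scheme (`"normalized"` or `"weighted"`).
#' @param power a [power_table()].
#' @param n_lambda,lambda_min_ratio penalty grid.
#' @param seed integer seed (k-means restarts).
#' @param secondary optional plug-in regressor evaluated on the group-
#'   lasso-reduced feature set: a list with functions
#'   `fit(Z, y) -> object` and `predict(object, Z) -> numeric`, applied
#'   per cluster to the standardized active-group columns. Failures skip
#'   the plug-in with a warning.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(rec, dh = 30, window = 5, stride = 1, K = 4,
                         scheme = "normalized", power = power_table(),
                         n_lambda = 40, lambda_min_ratio = 1e-4, seed = 1,
                         secondary = NULL) {
  if (nrow(rec$days) < 3) abort("need at least 2 training days and 1 test day")
  days <- sort(rec$days$day)
  test_day <- days[length(days)]
  train_days <- setdiff(days, test_day)
  design <- build_design(rec, dh = dh, window = window, stride = stride)
  train_rows <- which(design$day %in% train_days)
  activity <- fit_activity(design, train_rows, K = K, seed = seed)
  design <- assign_clusters(design, activity)
  test_rows <- which(design$day == test_day)
  test <- design[test_rows, ]

  cluster_fits <- vector("list", K)
  for (cl in seq_len(K)) {
    cluster_fits[cl] <- list(tryCatch(
      cv_select(design, train_days, cluster = cl, scheme = scheme,
                power = power, n_lambda = n_lambda,
                lambda_min_ratio = lambda_min_ratio),
      error = function(e) {
        warn(paste0("cluster ", cl, " skipped: ", conditionMessage(e)))
        NULL
      }))
  }
  fitted_cl <- which(!purrr::map_lgl(cluster_fits, is.null))

  # clustered test predictions
  pred_c <- rep(NA_real_, nrow(test))
  for (cl in fitted_cl) {
    sel <- which(test$cluster == cl)
    if (length(sel)) {
      pred_c[sel] <- predict(cluster_fits[[cl]]$model, test[sel, ])
    }
  }
  # rows of unfitted clusters fall back to the unclustered model below
  nc_fit <- cv_select(design, train_days, cluster = NA, scheme = scheme,
                      power = power, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio)
  pred_nc <- predict(nc_fit$model, test)
  pred_c[is.na(pred_c)] <- pred_nc[is.na(pred_c)]
  cp <- constant_predictor(design, test_rows,
                           train_mean = mean(design$y[train_rows]))

  metrics <- dplyr::bind_rows(
    dplyr::mutate(hr_metrics(test$y, pred_c), model = "clustered"),
    dplyr::mutate(hr_metrics(test$y, pred_nc), model = "unclustered"),
    dplyr::mutate(hr_metrics(test$y, cp), model = "constant_predictor"))
  metrics <- metrics[, c("model", setdiff(names(metrics), "model"))]

  per_cluster <- purrr::map_dfr(fitted_cl, function(cl) {
    sel <- which(test$cluster == cl)
    if (length(sel) < 2) {
      return(tibble::tibble(cluster = cl, n = length(sel),
                            small_sample = TRUE))
    }
    m <- hr_metrics(test$y[sel], pred_c[sel])
    dplyr::mutate(m, cluster = cl, small_sample = length(sel) < 30)
  })

  n_ci <- purrr::map_dbl(fitted_cl, ~ sum(test$cluster == .x, na.rm = TRUE))
  usable <- n_ci > 0
  pr <- power_report(
    setNames(purrr::map(cluster_fits[fitted_cl][usable], ~ .x$model$active),
             paste0("C", fitted_cl[usable])),
    n_ci[usable], power)
  nc_red <- current_reduction(nc_fit$model$active, power)

  tradeoffs <- purrr::map(fitted_cl, function(cl) {
    sel <- which(test$cluster == cl)
    if (length(sel) < 2) return(NULL)
    p <- path_rmse(cluster_fits[[cl]]$path, test[sel, ])
    tradeoff_curve(p, cluster_fits[[cl]]$lambda_opt, power)
  })
  names(tradeoffs) <- paste0("C", fitted_cl)
  nc_path <- path_rmse(nc_fit$path, test)
  tradeoffs$NC <- tradeoff_curve(nc_path, nc_fit$lambda_opt, power)

  secondary_metrics <- NULL
  if (!is.null(secondary)) {
    secondary_metrics <- tryCatch(
      eval_secondary(secondary, design, train_days, test, cluster_fits,
                     fitted_cl, nc_fit),
      error = function(e) {
        warn(paste0("secondary regressor skipped: ", conditionMessage(e)))
        NULL
      })
  }

  structure(list(
    dh = dh, scheme = scheme, K = K,
    train_days = train_days, test_day = test_day,
    activity = activity, cluster_fits = cluster_fits, nc_fit = nc_fit,
    metrics = metrics, per_cluster_metrics = per_cluster,
    power_report = pr, nc_reduction = nc_red,
    tradeoffs = tradeoffs, design = design,
    predictions = tibble::tibble(t = test$t, y = test$y,
                                 clustered = pred_c, unclustered = pred_nc,
                                 constant = as.numeric(cp),
                                 cluster = test$cluster),
    secondary_metrics = secondary_metrics),
    class = "pipeline_report")
}

# fit/predict plug-in on the standardized active-group feature set
eval_secondary <- function(plugin, design, train_days, test, cluster_fits,
                           fitted_cl, nc_fit) {
  pred <- rep(NA_real_, nrow(test))
  for (cl in fitted_cl) {
    model <- cluster_fits[[cl]]$model
    cols <- unlist(model$groups[model$active], use.names = FALSE)
    if (!length(cols)) next
    rows <- which(design$day %in% train_days & design$cluster == cl)
    Zt <- scale_cols(design[rows, ], cols, model)
    obj <- plugin$fit(Zt, design$y[rows])
    sel <- which(test$cluster == cl)
    if (length(sel)) pred[sel] <- plugin$predict(obj, scale_cols(test[sel, ], cols, model))
  }
  if (anyNA(pred)) {
    model <- nc_fit$model
    cols <- unlist(model$groups[model$active], use.names = FALSE)
    rows <- which(design$day %in% train_days)
    obj <- plugin$fit(scale_cols(design[rows, ], cols, model), design$y[rows])
    miss <- which(is.na(pred))
    pred[miss] <- plugin$predict(obj, scale_cols(test[miss, ], cols, model))
  }
  dplyr::mutate(hr_metrics(test$y, pred), model = "secondary")
}

scale_cols <- function(data, cols, model) {
  X <- as.matrix(data[, cols, drop = FALSE])
  sweep(sweep(X, 2, model$center[cols]), 2, model$scale[cols], "/")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> dh = ", x$dh, " s, ", x$scheme, " penalty, K = ",
      x$K, "\n", sep = "")
  cat("  train days: ", paste(x$train_days, collapse = ", "),
      "; test day: ", x$test_day, "\n", sep = "")
  print(x$metrics[, c("model", "mae", "rmse", "nrmse", "r_squared")])
  avg <- attr(x$power_report, "average")
  cat("  average current reduction: ", round(avg$delta_ma, 3), " mA (",
      round(avg$delta_pct, 2), "%)\n", sep = "")
  invisible(x)
}
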