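#' Tidy a fitted per-cluster heart-rate model
#'
#' @param x an `hr_model` from [fit_hr_model()] or [cv_select()].
#' @param ... unused.
#' @return Tibble with one row per coefficient: `sensor`, `term`,
#'   `estimate` (standardized units), `active`.
#' @export
tidy.hr_model <- function(x, ...) {
  purrr::imap_dfr(x$groups, function(cols, g) {
    tibble::tibble(sensor = g, term = cols, estimate = unname(x$beta[cols]),
                   active = g %in% x$active)
  })
}

#' @rdname tidy.hr_model
#' @return For `glance()`: one row with `lambda`, `scheme`, `cluster`,
#'   `n_active`, `n_train`, `objective`, `converged`.
#' @export
glance.hr_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, scheme = x$scheme, cluster = x$cluster,
                 n_active = length(x$active), n_train = x$n_train,
                 objective = x$objective, converged = x$converged)
}

#' Tidy a regularization path
#'
#' @param x a [lambda_path()].
#' @param ... unused.
#' @return The path's per-penalty tibble with the active sets expanded to a
#'   comma-separated string.
#' @export
tidy.lambda_path <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$active <- purrr::map_chr(out$active, paste, collapse = ",")
  out
}

#' @rdname tidy.lambda_path
#' @export
glance.lambda_path <- function(x, ...) {
  tibble::tibble(lambda_max = attr(x, "lambda_max"),
                 n_lambda = nrow(x),
                 scheme = attr(x, "scheme"),
                 cluster = attr(x, "cluster"))
}

#' Tidy an activity cluster model
#'
#' @param x an [fit_activity()] result.
#' @param ... unused.
#' @return Tibble with one row per cluster: `cluster`, `n_train`, and the
#'   centroid coordinates `dim1..dimd`.
#' @export
tidy.activity_model <- function(x, ...) {
  cent <- x$centroids
  colnames(cent) <- paste0("dim", seq_len(ncol(cent)))
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(x$K), n_train = x$sizes),
                   tibble::as_tibble(cent))
}

#' @rdname tidy.activity_model
#' @export
glance.activity_model <- function(x, ...) {
  tibble::tibble(K = x$K, context = x$context,
                 knn = x$lpp$knn, bandwidth = x$lpp$bandwidth)
}

#' Tidy a pipeline report
#'
#' @param x a [run_pipeline()] result.
#' @param ... unused.
#' @return The test-set metrics tibble (one row per model variant).
#' @export
tidy.pipeline_report <- function(x, ...) x$metrics

#' @rdname tidy.pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  avg <- attr(x$power_report, "average")
  tibble::tibble(dh = x$dh, scheme = x$scheme, K = x$K,
                 test_day = x$test_day,
                 rmse_clustered = x$metrics$rmse[x$metrics$model == "clustered"],
                 rmse_unclustered = x$metrics$rmse[x$metrics$model == "unclustered"],
                 avg_reduction_ma = avg$delta_ma,
                 avg_reduction_pct = avg$delta_pct,
                 nc_reduction_ma = x$nc_reduction$delta_ma)
}
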