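test_that("metrics match the hand-computed example and edge cases", {
  y <- c(60, 80, 100); yhat <- c(62, 77, 104)
  m <- hr_metrics(y, yhat)
  expect_equal(m$mae, 3)
  expect_equal(m$rmse, sqrt(29 / 3))
  expect_equal(m$nrmse, sqrt(29 / 3) / 40)
  expect_equal(m$r_squared, 1 - 29 / 800)
  perfect <- hr_metrics(y, y)
  expect_equal(unlist(perfect[c("mae", "rmse", "nrmse")]),
               c(mae = 0, rmse = 0, nrmse = 0))
  expect_equal(perfect$r_squared, 1)
  # mean predictor has exactly zero R^2
  expect_equal(hr_metrics(y, rep(mean(y), 3))$r_squared, 0)
  expect_error(hr_metrics(rep(5, 3), c(1, 2, 3)), "constant")
  expect_error(hr_metrics(1:3, 1:4), "equal length")
})

test_that("constant predictor is an exact lag of the response", {
  cfg <- sim_config(days = 1,
                    protocol = tibble::tibble(state = "walk", duration_s = 120))
  rec <- simulate_recording(cfg, seed = 1)
  d <- build_design(rec, dh = 30, window = 5)
  cp <- constant_predictor(d)
  y_grid <- rec$streams$hr$hr_bpm
  # y(t) is the raw sample at t - 1, so cp(t) = raw sample at t - 31
  expect_equal(cp, y_grid[d$t - 30])
  # linear-ramp response: lag error equals slope * dh
  d$y <- d$t
  d$hr__lag <- d$t - 30
  expect_equal(hr_metrics(d$y, constant_predictor(d))$mae, 30)
  # dh = Inf falls back to the training mean, flagged
  dinf <- build_design(rec, dh = Inf, window = 5)
  cpi <- constant_predictor(dinf, train_mean = 95)
  expect_true(all(cpi == 95))
  expect_true(attr(cpi, "flat"))
  expect_error(constant_predictor(dinf), "training mean")
})

test_that("pipeline report has the expected structure on synthetic data", {
  rec <- short_recording(days = 3, seed = 31)
  rep <- suppressWarnings(
    run_pipeline(rec, dh = 10, K = 4, n_lambda = 12, seed = 1))
  expect_s3_class(rep, "pipeline_report")
  expect_length(rep$cluster_fits, 4)
  expect_setequal(rep$metrics$model,
                  c("clustered", "unclustered", "constant_predictor"))
  avg <- attr(rep$power_report, "average")
  expect_gte(avg$delta_ma, min(rep$power_report$delta_ma))
  expect_lte(avg$delta_ma, max(rep$power_report$delta_ma))
  expect_false(anyNA(rep$predictions$clustered))
  # pooled clustered RMSE equals the size-weighted quadratic mean of the
  # per-cluster RMSEs
  pc <- rep$per_cluster_metrics[!is.na(rep$per_cluster_metrics$rmse), ]
  pooled <- sqrt(sum(pc$n * pc$rmse^2) / sum(pc$n))
  covered <- rep$predictions$cluster %in% pc$cluster
  direct <- sqrt(mean((rep$predictions$clustered[covered] -
                         rep$predictions$y[covered])^2))
  expect_equal(pooled, direct, tolerance = 1e-10)
})

test_that("pipeline is deterministic for a fixed seed", {
  rec <- short_recording(days = 3, seed = 32)
  a <- suppressWarnings(run_pipeline(rec, dh = 10, K = 2, n_lambda = 8,
                                     seed = 5))
  b <- suppressWarnings(run_pipeline(rec, dh = 10, K = 2, n_lambda = 8,
                                     seed = 5))
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$power_report$delta_ma, b$power_report$delta_ma)
})

test_that("K = 1 clustering reduces to the unclustered model", {
  rec <- short_recording(days = 3, seed = 33)
  rep <- suppressWarnings(run_pipeline(rec, dh = 10, K = 1, n_lambda = 10,
                                       seed = 1))
  expect_equal(rep$predictions$clustered, rep$predictions$unclustered)
  expect_equal(
    rep$metrics$rmse[rep$metrics$model == "clustered"],
    rep$metrics$rmse[rep$metrics$model == "unclustered"])
})

test_that("secondary regressor plug-ins run on the reduced feature set", {
  rec <- short_recording(days = 3, seed = 34)
  # ridge-stabilized linear plug-in on the reduced feature set stays in the
  # same accuracy league as the penalized model (same features)
  glp <- list(
    fit = function(Z, y) {
      # mild ridge: within one activity cluster some window features are
      # nearly constant on the training days, and plain least squares
      # loads them into instability on the held-out day
      X <- cbind(1, Z)
      pen <- diag(c(0, rep(0.02 * nrow(X), ncol(Z))))
      qr.solve(crossprod(X) + pen, crossprod(X, y))
    },
    predict = function(obj, Z) as.numeric(cbind(1, Z) %*% obj))
  rep <- suppressWarnings(
    run_pipeline(rec, dh = 10, K = 2, n_lambda = 10, seed = 1,
                 secondary = glp))
  expect_false(is.null(rep$secondary_metrics))
  expect_lt(rep$secondary_metrics$rmse,
            2 * rep$metrics$rmse[rep$metrics$model == "clustered"] + 2)
  # without clustering, a training-mean plug-in explains (essentially)
  # none of the test variance
  mp <- list(fit = function(Z, y) mean(y),
             predict = function(obj, Z) rep(obj, nrow(Z)))
  rep2 <- suppressWarnings(
    run_pipeline(rec, dh = 10, K = 1, n_lambda = 10, seed = 1,
                 secondary = mp))
  expect_lt(rep2$secondary_metrics$r_squared, 0.1)
  # failing plug-in is skipped with a warning, pipeline still completes
  bad <- list(fit = function(Z, y) stop("boom"), predict = function(o, Z) 0)
  expect_warning(
    rep3 <- run_pipeline(rec, dh = 10, K = 2, n_lambda = 10, seed = 1,
                         secondary = bad),
    "skipped")
  expect_null(rep3$secondary_metrics)
})

test_that("tidiers return well-formed tibbles", {
  rec <- short_recording(days = 3, seed = 35)
  rep <- suppressWarnings(run_pipeline(rec, dh = 10, K = 2, n_lambda = 8,
                                       seed = 1))
  fit1 <- purrr::detect(rep$cluster_fits, Negate(is.null))
  expect_false(is.null(fit1))
  td <- tidy(fit1$model)
  expect_true(all(c("sensor", "term", "estimate", "active") %in% names(td)))
  expect_equal(nrow(td), length(unlist(fit1$model$groups)))
  gl <- glance(fit1$model)
  expect_equal(nrow(gl), 1)
  expect_equal(nrow(tidy(rep$activity)), 2)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(glance(rep)), 1)
  # plots build without evaluation errors
  expect_s3_class(autoplot(path_rmse(rep$nc_fit$path, rep$design)),
                  "ggplot")
  expect_s3_class(autoplot(rep$tradeoffs$NC), "ggplot")
  expect_s3_class(plot_dropout_levels(dropout_levels(rep$nc_fit$path)),
                  "ggplot")
  expect_s3_class(plot_predictions(rep), "ggplot")
})
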