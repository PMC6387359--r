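test_that("lambda_max is the exact boundary of the all-zero solution", {
  set.seed(1)
  Z <- scale(matrix(rnorm(50 * 6), 50))
  colnames(Z) <- paste0("v", 1:6)
  y <- scale(rnorm(50) + Z[, 1])[, 1]
  groups <- list(a = c("v1", "v2"), b = c("v3", "v4"), c = c("v5", "v6"))
  ck <- penalty_weights(groups)
  lmax <- lambda_max(Z, y, groups, ck)
  expect_equal(lmax, max(sapply(groups, function(g) {
    2 * sqrt(sum(crossprod(Z[, g], y)^2)) * sqrt(2)  # /sqrt(1/2)
  })))
  empty <- group_lasso(Z, y, groups, lmax * (1 + 1e-10), ck)
  expect_length(empty$active, 0)
  just_below <- group_lasso(Z, y, groups, lmax * 0.999, ck)
  expect_gte(length(just_below$active), 1)
  # orthogonal response
  y0 <- residuals(lm(y ~ Z - 1))
  y0 <- y0 / sd(y0)
  expect_lt(lambda_max(Z, y0, groups, ck), 1e-10 * lmax)
  # scaling ck by 4 halves that group's contribution
  ck2 <- ck; ck2["a"] <- 4 * ck["a"]
  la <- 2 * sqrt(sum(crossprod(Z[, groups$a], y)^2))
  expect_equal(lambda_max(Z, y, list(a = groups$a), ck2["a"]),
               la / sqrt(ck2[["a"]]))
  expect_error(lambda_max(Z, rep(1, 50), groups, ck), "zero variance")
})

test_that("single orthonormal group reproduces the hand KKT boundary", {
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(30 * 3), 30)))
  y <- rnorm(30)
  groups <- list(g = 1:3)
  expect_equal(lambda_max(Q, y, groups, c(g = 1)),
               2 * sqrt(sum(crossprod(Q, y)^2)))
})

test_that("lambda = 0 returns least squares, including minimum-norm", {
  set.seed(3)
  Z <- scale(matrix(rnorm(40 * 5), 40)); colnames(Z) <- paste0("v", 1:5)
  y <- rnorm(40)
  groups <- list(a = paste0("v", 1:2), b = paste0("v", 3:5))
  fit <- group_lasso(Z, y, groups, 0, penalty_weights(groups))
  expect_equal(unname(fit$beta), unname(qr.solve(Z, y)), tolerance = 1e-5)
  # rank-deficient: duplicated columns, minimum-norm solution
  Zr <- cbind(Z[, 1:3], Z[, 3]); colnames(Zr) <- paste0("v", 1:4)
  fitr <- group_lasso(Zr, y, list(a = paste0("v", 1:4)), 0, c(a = 1))
  sv <- svd(Zr)
  bmn <- sv$v %*% ((crossprod(sv$u, y) / sv$d) * (sv$d > 1e-10))
  expect_equal(unname(fitr$beta), as.numeric(bmn), tolerance = 1e-5)
})

test_that("all features in one group matches the FISTA oracle (ridge-type)", {
  inst <- random_instance(10, n = 10, p_groups = 5)
  groups <- list(g = colnames(inst$Z))
  ck <- c(g = 1)
  lmax <- lambda_max(inst$Z, inst$y, groups, ck)
  for (lam in lmax * c(0.5, 0.1, 0.01)) {
    mine <- group_lasso(inst$Z, inst$y, groups, lam, ck)
    oracle <- fista_group_lasso(inst$Z, inst$y, groups, lam, ck)
    expect_equal(mine$objective, oracle$objective, tolerance = 1e-8)
  }
})

test_that("singleton groups with unit weights match the scalar lasso oracle", {
  inst <- random_instance(11, n = 20, p_groups = c(1, 1, 1))
  groups <- inst$groups
  ck <- setNames(rep(1, 3), names(groups))
  lmax <- lambda_max(inst$Z, inst$y, groups, ck)
  for (lam in lmax * c(0.6, 0.2, 0.05)) {
    mine <- group_lasso(inst$Z, inst$y, groups, lam, ck)
    oracle <- cd_lasso(inst$Z, inst$y, lam)
    expect_equal(unname(mine$beta), oracle, tolerance = 1e-6)
  }
})

test_that("every fit carries a passing KKT certificate", {
  for (s in 1:10) {
    inst <- random_instance(s)
    ck <- penalty_weights(inst$groups)
    lmax <- lambda_max(inst$Z, inst$y, inst$groups, ck)
    for (frac in c(0.7, 0.2, 0.03)) {
      fit <- group_lasso(inst$Z, inst$y, inst$groups, lmax * frac, ck)
      cert <- kkt_check(inst$Z, inst$y, fit$beta, inst$groups, ck, lmax * frac)
      expect_true(all(cert$ok),
                  info = paste("seed", s, "frac", frac))
    }
  }
})

test_that("solution is invariant to within-group column permutation", {
  inst <- random_instance(12, n = 30, p_groups = c(4, 3))
  ck <- penalty_weights(inst$groups)
  lam <- lambda_max(inst$Z, inst$y, inst$groups, ck) * 0.2
  fit <- group_lasso(inst$Z, inst$y, inst$groups, lam, ck)
  perm <- c(3, 1, 4, 2, 6, 7, 5)   # permute inside each group
  Zp <- inst$Z[, perm]
  fitp <- group_lasso(Zp, inst$y, list(g1 = colnames(Zp)[1:4],
                                       g2 = colnames(Zp)[5:7]), lam, ck)
  expect_equal(fitp$beta[colnames(inst$Z)], fit$beta, tolerance = 1e-8)
})

test_that("warm-started path has non-increasing active-set growth and sane objectives", {
  rec <- short_recording(days = 2, seed = 4)
  d <- build_design(rec, dh = 10, window = 5)
  p <- suppressWarnings(lambda_path(d, n_lambda = 20))
  expect_length(p$active[[1]], 0)
  # convexity: refitting cold at a grid point reaches the same objective
  std <- attr(p, "std")
  ck <- attr(p, "ck")
  i <- 10
  cold <- group_lasso(std$Z, std$y, std$groups, p$lambda[i], ck)
  expect_equal(cold$objective, p$objective[i],
               tolerance = 1e-6 * max(1, p$objective[i]))
  expect_true(all(diff(p$lambda) < 0))
})

test_that("planted groups are the last to leave the path", {
  rec <- simulate_recording(recovery_config(days = 1, day_scale = 10), seed = 3)
  rec <- plant_linear_response(rec, recovery_planted(), seed = 3,
                               window = 5, dh = 10)
  d <- build_design(rec, dh = 10, window = 5)
  p <- suppressWarnings(lambda_path(d, n_lambda = 30))
  lev <- dropout_levels(p)
  planted <- attr(rec, "true_support")
  expect_gt(min(lev$lambda_level[lev$sensor %in% planted]),
            max(lev$lambda_level[!lev$sensor %in% planted]))
})

test_that("predictions destandardize correctly and respect duty-cycling", {
  rec <- short_recording(days = 2, seed = 5)
  d <- build_design(rec, dh = 10, window = 5)
  std <- standardize_design(d)
  ck <- penalty_weights(std$groups)
  lmax <- lambda_max(std$Z, std$y, std$groups, ck)
  model <- suppressWarnings(fit_hr_model(d, lambda = lmax * 0.05))
  # in-sample predictions match the fitted values computed by hand
  pred <- predict(model, d)
  cols <- colnames(std$Z)
  Zs <- sweep(sweep(as.matrix(d[cols]), 2, model$center[cols]), 2,
              model$scale[cols], "/")
  byhand <- model$y_center + model$y_scale * as.numeric(Zs %*% model$beta[cols])
  expect_equal(pred, byhand)
  # empty model predicts the training mean
  empty <- suppressWarnings(fit_hr_model(d, lambda = lmax * 2))
  expect_equal(predict(empty, d), rep(mean(d$y), nrow(d)))
  # dropping an inactive sensor's columns changes nothing
  inactive <- setdiff(names(model$groups), model$active)
  if (length(inactive)) {
    drop_cols <- model$groups[[inactive[1]]]
    expect_equal(predict(model, d[setdiff(names(d), drop_cols)]), pred)
  }
  # dropping an active sensor's columns errors naming it
  act <- model$active[1]
  expect_error(predict(model, d[setdiff(names(d), model$groups[[act]])]),
               act)
})

test_that("day-wise CV selects a near-null model for pure-noise response", {
  rec <- short_recording(days = 3, seed = 6)
  d <- build_design(rec, dh = 10, window = 5)
  set.seed(99)
  d$y <- rnorm(nrow(d))
  cv <- suppressWarnings(cv_select(d, 1:3, cluster = NA, n_lambda = 20))
  # null-model RMSE on held-out folds
  null_rmse <- cv$path$cv_rmse[1]
  expect_lte(min(cv$path$cv_rmse), null_rmse)
  expect_lte(null_rmse - min(cv$path$cv_rmse), sd(d$y))
  expect_lte(length(cv$model$active), 2)
})

test_that("duplicating every training row leaves the selected index unchanged", {
  rec <- short_recording(days = 2, seed = 7)
  d <- build_design(rec, dh = 10, window = 5)
  cv1 <- suppressWarnings(cv_select(d, 1:2, cluster = NA, n_lambda = 15))
  d2 <- dplyr::bind_rows(d, d)
  attr(d2, "groups") <- attr(d, "groups")
  attr(d2, "dh") <- attr(d, "dh")
  class(d2) <- class(d)
  cv2 <- suppressWarnings(cv_select(d2, 1:2, cluster = NA, n_lambda = 15))
  i1 <- which.min(abs(cv1$path$lambda - cv1$lambda_opt))
  i2 <- which.min(abs(cv2$path$lambda - cv2$lambda_opt))
  expect_equal(i2, i1)
  expect_equal(cv2$lambda_opt / cv1$lambda_opt, 2, tolerance = 1e-2)
  expect_setequal(cv2$model$active, cv1$model$active)
})

test_that("a cluster absent from one day skips the fold with a warning", {
  rec <- short_recording(days = 3, seed = 8)
  d <- build_design(rec, dh = 10, window = 5)
  d$cluster <- 1L
  d$cluster[d$day == 2] <- 2L
  expect_warning(cv_select(d, 1:3, cluster = 1, n_lambda = 8), "fold skipped")
  expect_error(suppressWarnings(cv_select(d, 1:3, cluster = 9, n_lambda = 8)),
               "absent")
})
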