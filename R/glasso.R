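#' Per-group penalty weights
#'
#' The penalty in the group-lasso objective is
#' `lambda * sum_k sqrt(c_k) * ||beta_k||_2`, the weighted group norm
#' `||beta_k||_{W_k}` with `W_k = c_k I`. The `normalized` scheme uses
#' `c_k = 1 / M_k` (M_k features in group k), weighting every sensor
#' equally regardless of how many features it contributes; the `weighted`
#' scheme uses `c_k = P_k / M_k`, additionally penalizing each sensor by
#' its average current draw `P_k` (mA) so power-hungry sensors are
#' preferentially excluded.
#'
#' @param groups named list of feature-column names per group.
#' @param scheme `"normalized"` or `"weighted"`.
#' @param power a [power_table()]; required for the weighted scheme.
#' @return Named numeric vector `c_k` (one entry per group).
#' @export
penalty_weights <- function(groups, scheme = c("normalized", "weighted"),
                            power = NULL) {
  scheme <- match.arg(scheme)
  M <- purrr::map_dbl(groups, length)
  if (scheme == "normalized") return(1 / M)
  if (is.null(power)) abort("weighted scheme needs a power table")
  P <- setNames(power$current_ma, power$sensor)
  missing <- setdiff(names(groups), names(P))
  if (length(missing)) {
    abort(paste0("power table has no entry for: ", paste(missing, collapse = ", ")))
  }
  P[names(groups)] / M
}

#' Smallest penalty that zeroes every group
#'
#' For the objective `||y - Z beta||^2 + lambda sum_k sqrt(c_k) ||beta_k||`,
#' the all-zero solution is optimal iff
#' `lambda >= max_k 2 ||Z_k' y|| / sqrt(c_k)`.
#'
#' @param Z standardized design matrix.
#' @param y standardized response.
#' @param groups named list of column indices (or names) per group.
#' @param ck per-group penalty weights from [penalty_weights()].
#' @return The boundary value `lambda_max`.
#' @export
lambda_max <- function(Z, y, groups, ck) {
  if (sd(y) < 1e-12) abort("response has zero variance")
  max(purrr::map_dbl(seq_along(groups), function(k) {
    Zk <- Z[, groups[[k]], drop = FALSE]
    2 * sqrt(sum(crossprod(Zk, y)^2)) / sqrt(ck[k])
  }))
}

gl_objective <- function(Z, y, beta, groups, ck, lambda) {
  r <- y - Z %*% beta
  pen <- sum(purrr::map_dbl(seq_along(groups), function(k) {
    sqrt(ck[k]) * sqrt(sum(beta[groups[[k]]]^2))
  }))
  sum(r^2) + lambda * pen
}

#' Group lasso by block coordinate descent
#'
#' Minimizes `||y - Z beta||^2 + lambda sum_k sqrt(c_k) ||beta_k||_2`
#' (penalty not divided by N) by cyclic blockwise proximal updates with a
#' per-group Lipschitz majorization. At `lambda = 0` the minimum-norm least
#' squares solution is returned directly. Convergence is declared when the
#' largest coefficient change in a sweep falls below `tol`.
#'
#' @param Z standardized design matrix (N x p).
#' @param y standardized response (length N).
#' @param groups named list of column names/indices per group.
#' @param lambda penalty weight (>= 0).
#' @param ck per-group weights, see [penalty_weights()].
#' @param beta0 optional warm-start coefficients.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_sweeps sweep budget; exceeding it warns and flags the fit.
#' @return List with `beta` (named), `active` (group names with nonzero
#'   coefficient blocks), `objective`, `converged`, `sweeps`.
#' @export
group_lasso <- function(Z, y, groups, lambda, ck, beta0 = NULL,
                        tol = 1e-6, max_sweeps = 10000) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z)) || !all(is.finite(y))) abort("non-finite inputs")
  p <- ncol(Z)
  idx <- purrr::map(groups, function(g) {
    if (is.character(g)) match(g, colnames(Z)) else as.integer(g)
  })
  if (lambda == 0) {
    sv <- svd(Z)
    pos <- sv$d > max(dim(Z)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- as.numeric(beta)
    names(beta) <- colnames(Z)
    active <- names(groups)[purrr::map_lgl(idx, ~ any(abs(beta[.x]) > 1e-12))]
    return(list(beta = beta, active = active,
                objective = gl_objective(Z, y, beta, idx, ck, lambda),
                converged = TRUE, sweeps = 0L))
  }
  # Gram formulation: all sweeps work on p x p cross-products, so the cost
  # per sweep is independent of N
  G <- crossprod(Z)
  q <- as.numeric(crossprod(Z, y))
  # per-group eigendecompositions for exact block minimization
  eig <- purrr::map(idx, function(ix) {
    e <- eigen(G[ix, ix, drop = FALSE], symmetric = TRUE)
    e$values <- pmax(e$values, 0)
    e
  })
  beta <- if (is.null(beta0)) rep(0, p) else as.numeric(beta0)
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    delta_max <- 0
    for (k in seq_along(idx)) {
      ix <- idx[[k]]
      bk <- beta[ix]
      # partial-residual correlation: Z_k'(y - Z_{-k} beta_{-k})
      qk <- q[ix] - as.numeric(G[ix, , drop = FALSE] %*% beta) +
        as.numeric(G[ix, ix, drop = FALSE] %*% bk)
      s <- lambda * sqrt(ck[k])
      bk_new <- block_minimize(qk, eig[[k]], s)
      db <- bk_new - bk
      if (any(db != 0)) {
        beta[ix] <- bk_new
        delta_max <- max(delta_max, max(abs(db)))
      }
    }
    if (delta_max < tol) { converged <- TRUE; break }
  }
  if (!converged) warn("group lasso did not converge within the sweep budget")
  names(beta) <- colnames(Z)
  active <- names(groups)[purrr::map_lgl(idx, ~ any(abs(beta[.x]) > 0))]
  list(beta = beta, active = active,
       objective = gl_objective(Z, y, beta, idx, ck, lambda),
       converged = converged, sweeps = sweeps)
}

# exact minimizer of ||y - Z_k b||^2 + s ||b|| given q = Z_k' (partial
# residual) and the eigendecomposition of G_k = Z_k'Z_k: the stationarity
# condition (2 G_k + (s / ||b||) I) b = 2 q reduces, in the eigenbasis
# w = V' q, to the scalar root of h(t) - t with
# h(t) = || 2 w t / (2 g t + s) ||, the norm the solution must have
block_minimize <- function(q, eig, s) {
  if (s <= 0) {
    # unpenalized: least-squares on the block
    g <- eig$values
    w <- as.numeric(crossprod(eig$vectors, q))
    pos <- g > max(g, 1) * 1e-12
    b <- rep(0, length(w)); b[pos] <- w[pos] / g[pos]
    return(as.numeric(eig$vectors %*% b))
  }
  if (2 * sqrt(sum(q^2)) <= s * (1 + 1e-10)) return(rep(0, length(q)))
  # floor the eigenvalues: a singular block has multiple minimizers and the
  # floor selects a near-minimum-norm one
  g <- pmax(eig$values, 1e-12 * max(eig$values[1], 1))
  w <- as.numeric(crossprod(eig$vectors, q))
  # in terms of nu = s / ||b||: b_i = 2 w_i / (2 g_i + nu) and
  # nu * ||b(nu)|| is monotone increasing with limit 2||w|| > s
  f <- function(nu) sqrt(sum((2 * w * nu / (2 * g + nu))^2)) - s
  lo <- min(s * 1e-12, min(g) * 1e-3)
  while (f(lo) > 0) lo <- lo / 10
  hi <- s
  while (f(hi) < 0) hi <- hi * 10
  nu <- stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
  b <- 2 * w / (2 * g + nu)
  as.numeric(eig$vectors %*% b)
}

#' KKT optimality certificate for a group-lasso solution
#'
#' Active groups must satisfy `2 Z_k' r = lambda sqrt(c_k) beta_k /
#' ||beta_k||`; inactive groups must satisfy `||2 Z_k' r|| <= lambda
#' sqrt(c_k)`.
#'
#' @param Z,y,groups,ck,lambda as in [group_lasso()].
#' @param beta coefficient vector.
#' @param tol_active absolute tolerance on the active-group stationarity
#'   residual.
#' @param tol_inactive relative slack on the inactive-group bound.
#' @return Tibble with one row per group: `group`, `active`, `residual`,
#'   `ok`.
#' @export
kkt_check <- function(Z, y, beta, groups, ck, lambda,
                      tol_active = 1e-4, tol_inactive = 1e-6) {
  Z <- as.matrix(Z)
  idx <- purrr::map(groups, function(g) {
    if (is.character(g)) match(g, colnames(Z)) else as.integer(g)
  })
  r <- y - Z %*% beta
  purrr::map_dfr(seq_along(idx), function(k) {
    ix <- idx[[k]]
    g <- as.numeric(2 * crossprod(Z[, ix, drop = FALSE], r))
    bk <- beta[ix]
    nb <- sqrt(sum(bk^2))
    if (nb > 0) {
      res <- sqrt(sum((g - lambda * sqrt(ck[k]) * bk / nb)^2))
      ok <- res <= tol_active
    } else {
      res <- sqrt(sum(g^2))
      ok <- res <= lambda * sqrt(ck[k]) * (1 + tol_inactive)
    }
    tibble::tibble(group = names(groups)[k], active = nb > 0,
                   residual = res, ok = ok)
  })
}

#' Fit a per-cluster heart-rate model at one penalty value
#'
#' Standardizes the design over the given rows, drops zero-variance
#' columns (with a warning naming them), and fits [group_lasso()]. The
#' intercept is handled by centering and never penalized; predictions are
#' affine in the raw features.
#'
#' @param design a [build_design()] result.
#' @param rows training row indices.
#' @param lambda penalty value.
#' @param scheme penalty scheme, see [penalty_weights()].
#' @param power optional [power_table()] for the weighted scheme.
#' @param cluster cluster index this model serves (NA for unclustered).
#' @param ... passed to [group_lasso()].
#' @return An object of class `hr_model`.
#' @export
fit_hr_model <- function(design, rows = seq_len(nrow(design)), lambda,
                         scheme = "normalized", power = NULL,
                         cluster = NA_integer_, ...) {
  std <- standardize_design(design, rows)
  if (length(std$dropped)) {
    warn(paste0("dropping zero-variance columns: ",
                paste(std$dropped, collapse = ", ")))
  }
  ck <- penalty_weights(std$groups, scheme, power)
  fit <- group_lasso(std$Z, std$y, std$groups, lambda, ck, ...)
  structure(list(
    beta = fit$beta, active = fit$active, lambda = lambda, scheme = scheme,
    ck = ck, groups = std$groups, cluster = cluster,
    center = std$center, scale = std$scale,
    y_center = std$y_center, y_scale = std$y_scale,
    dropped = std$dropped, dh = attr(design, "dh"),
    converged = fit$converged, objective = fit$objective,
    n_train = length(rows)),
    class = "hr_model")
}

#' Predict heart rate (bpm) from raw design rows
#'
#' Standardized affine prediction, destandardized to bpm. Feature columns
#' of inactive (duty-cycled) sensors may be absent; missing columns of an
#' active sensor raise an error naming it.
#'
#' @param object an `hr_model`.
#' @param newdata design rows (tibble with feature columns).
#' @param ... unused.
#' @return Numeric vector of predictions in bpm.
#' @export
predict.hr_model <- function(object, newdata, ...) {
  need <- unlist(object$groups[object$active], use.names = FALSE)
  for (g in object$active) {
    miss <- setdiff(object$groups[[g]], names(newdata))
    if (length(miss)) {
      abort(paste0("rows are missing features of active sensor '", g, "': ",
                   paste(miss, collapse = ", ")))
    }
  }
  if (length(need) == 0L) {
    return(rep(object$y_center, nrow(newdata)))
  }
  X <- as.matrix(newdata[, need, drop = FALSE])
  Z <- sweep(sweep(X, 2, object$center[need]), 2, object$scale[need], "/")
  as.numeric(object$y_center + object$y_scale * (Z %*% object$beta[need]))
}

#' Regularization path of the group lasso
#'
#' Fits a log-spaced descending grid from `lambda_max` down to
#' `lambda_max * lambda_min_ratio` with warm starts, recording active sets
#' and objectives.
#'
#' @param design,rows,scheme,power,cluster as in [fit_hr_model()].
#' @param n_lambda grid size (>= 2).
#' @param lambda_min_ratio ratio of the smallest to the largest grid value.
#' @return An object of class `lambda_path`: tibble columns `lambda`,
#'   `n_active`, `objective`, `active` (list), plus attributes with the
#'   coefficient matrix and standardization.
#' @export
lambda_path <- function(design, rows = seq_len(nrow(design)),
                        scheme = "normalized", power = NULL,
                        n_lambda = 40, lambda_min_ratio = 1e-4,
                        cluster = NA_integer_) {
  if (n_lambda < 2) abort("n_lambda must be at least 2")
  std <- standardize_design(design, rows)
  ck <- penalty_weights(std$groups, scheme, power)
  lmax <- lambda_max(std$Z, std$y, std$groups, ck)
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  betas <- matrix(0, ncol(std$Z), n_lambda,
                  dimnames = list(colnames(std$Z), NULL))
  act <- vector("list", n_lambda)
  obj <- numeric(n_lambda)
  beta0 <- NULL
  for (i in seq_len(n_lambda)) {
    fit <- group_lasso(std$Z, std$y, std$groups, grid[i], ck, beta0 = beta0)
    betas[, i] <- fit$beta
    act[[i]] <- fit$active
    obj[i] <- fit$objective
    beta0 <- fit$beta
  }
  out <- tibble::tibble(lambda = grid,
                        n_active = purrr::map_int(act, length),
                        objective = obj, active = act)
  structure(out, betas = betas, std = std, ck = ck, scheme = scheme,
            lambda_max = lmax, cluster = cluster, dh = attr(design, "dh"),
            class = c("lambda_path", class(out)))
}

# predictions in bpm for every lambda of a path, on raw design rows
path_predict <- function(path, newdata) {
  std <- attr(path, "std")
  betas <- attr(path, "betas")
  cols <- rownames(betas)
  X <- as.matrix(newdata[, cols, drop = FALSE])
  Z <- sweep(sweep(X, 2, std$center[cols]), 2, std$scale[cols], "/")
  std$y_center + std$y_scale * (Z %*% betas)
}

#' Attach held-out RMSE to a path
#'
#' @param path a [lambda_path()].
#' @param newdata design rows to evaluate on.
#' @param col name of the RMSE column to add.
#' @return The path with an RMSE column (bpm).
#' @export
path_rmse <- function(path, newdata, col = "test_rmse") {
  pred <- path_predict(path, newdata)
  path[[col]] <- apply(pred, 2, function(p) sqrt(mean((p - newdata$y)^2)))
  path
}

#' Day-wise cross-validated penalty selection
#'
#' Permutes the training days as folds: for each fold the path is fitted on
#' the other days' rows of the cluster and evaluated (RMSE, bpm) on the
#' held-out day's rows; the penalty minimizing the mean RMSE across folds
#' is selected (ties break to the larger penalty) and the final model is
#' refitted on all training days. The grid is anchored at the all-training
#' `lambda_max` so folds share it. A cluster absent from some day skips
#' that fold with a warning; absent from every day is an error.
#'
#' @param design a [build_design()] result with clusters assigned.
#' @param train_days integer vector of training day indices (>= 2).
#' @param cluster cluster index to fit, or `NA` for all rows (unclustered).
#' @param scheme,power penalty scheme and power table.
#' @param n_lambda,lambda_min_ratio grid, see [lambda_path()].
#' @return List of class `cv_fit`: `lambda_opt`, `path` (all-training path
#'   with `cv_rmse`), `model` (refit [fit_hr_model()]), `folds`.
#' @export
cv_select <- function(design, train_days, cluster = NA_integer_,
                      scheme = "normalized", power = NULL,
                      n_lambda = 40, lambda_min_ratio = 1e-4) {
  if (length(train_days) < 2) abort("need at least 2 training days")
  in_cluster <- if (is.na(cluster)) rep(TRUE, nrow(design)) else
    !is.na(design$cluster) & design$cluster == cluster
  train_rows <- which(design$day %in% train_days & in_cluster)
  if (!length(train_rows)) abort("cluster absent from all training days")
  path <- lambda_path(design, train_rows, scheme = scheme, power = power,
                      n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                      cluster = cluster)
  grid <- path$lambda
  fold_rmse <- matrix(NA_real_, length(train_days), length(grid))
  for (f in seq_along(train_days)) {
    held <- train_days[f]
    fit_rows <- which(design$day %in% setdiff(train_days, held) & in_cluster)
    val_rows <- which(design$day == held & in_cluster)
    if (!length(fit_rows) || !length(val_rows)) {
      warn(paste0("cluster ", cluster, " absent from day ", held,
                  "; fold skipped"))
      next
    }
    std <- standardize_design(design, fit_rows)
    ck <- penalty_weights(std$groups, scheme, power)
    beta0 <- NULL
    val <- design[val_rows, ]
    Xv <- as.matrix(val[, colnames(std$Z), drop = FALSE])
    Zv <- sweep(sweep(Xv, 2, std$center), 2, std$scale, "/")
    for (i in seq_along(grid)) {
      fit <- group_lasso(std$Z, std$y, std$groups, grid[i], ck, beta0 = beta0)
      beta0 <- fit$beta
      pred <- std$y_center + std$y_scale * as.numeric(Zv %*% fit$beta)
      fold_rmse[f, i] <- sqrt(mean((pred - val$y)^2))
    }
  }
  if (all(is.na(fold_rmse))) abort("no usable cross-validation folds")
  cv <- colMeans(fold_rmse, na.rm = TRUE)
  path$cv_rmse <- cv
  i_opt <- which.min(cv)            # descending grid: first min = largest lambda
  lambda_opt <- grid[i_opt]
  model <- suppressWarnings(
    fit_hr_model(design, train_rows, lambda = lambda_opt, scheme = scheme,
                 power = power, cluster = cluster))
  structure(list(lambda_opt = lambda_opt, path = path, model = model,
                 folds = train_days, cluster = cluster),
            class = "cv_fit")
}
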