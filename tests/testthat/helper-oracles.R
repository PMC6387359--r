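# Independent solvers used to cross-check the block-coordinate-descent
# group lasso. Both minimize ||y - Z beta||^2 + lambda * sum_k sqrt(ck) ||beta_k||.

# proximal-gradient (FISTA) oracle
fista_group_lasso <- function(Z, y, groups, lambda, ck, iters = 20000,
                              tol = 1e-12) {
  Z <- as.matrix(Z)
  p <- ncol(Z)
  idx <- lapply(groups, function(g) {
    if (is.character(g)) match(g, colnames(Z)) else as.integer(g)
  })
  L <- 2 * max(eigen(crossprod(Z), symmetric = TRUE, only.values = TRUE)$values)
  prox <- function(b) {
    for (k in seq_along(idx)) {
      ix <- idx[[k]]
      nb <- sqrt(sum(b[ix]^2))
      thr <- lambda * sqrt(ck[k]) / L
      b[ix] <- if (nb <= thr) 0 else b[ix] * (1 - thr / nb)
    }
    b
  }
  obj <- function(b) {
    pen <- sum(vapply(seq_along(idx), function(k) {
      sqrt(ck[k]) * sqrt(sum(b[idx[[k]]]^2))
    }, 0))
    sum((y - Z %*% b)^2) + lambda * pen
  }
  b <- rep(0, p); v <- b; t_k <- 1
  o_prev <- obj(b)
  for (i in seq_len(iters)) {
    grad <- -2 * as.numeric(crossprod(Z, y - Z %*% v))
    b_new <- prox(v - grad / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    v <- b_new + ((t_k - 1) / t_new) * (b_new - b)
    b <- b_new; t_k <- t_new
    if (i %% 50 == 0) {
      o <- obj(b)
      if (abs(o_prev - o) < tol * max(1, o)) break
      o_prev <- o
    }
  }
  list(beta = b, objective = obj(b))
}

# scalar coordinate-descent lasso oracle for singleton groups with ck = 1:
# the penalty reduces to lambda * sum_j |beta_j|
cd_lasso <- function(Z, y, lambda, iters = 10000, tol = 1e-12) {
  Z <- as.matrix(Z)
  p <- ncol(Z)
  b <- rep(0, p)
  zz <- colSums(Z^2)
  r <- y - Z %*% b
  for (it in seq_len(iters)) {
    dmax <- 0
    for (j in seq_len(p)) {
      rho <- sum(Z[, j] * r) + zz[j] * b[j]
      bj <- sign(rho) * max(0, abs(rho) - lambda / 2) / zz[j]
      if (bj != b[j]) {
        r <- r - Z[, j] * (bj - b[j])
        dmax <- max(dmax, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (dmax < tol) break
  }
  b
}

# random small grouped instance
random_instance <- function(seed, n = NULL, p_groups = NULL) {
  set.seed(seed)
  n <- n %||% sample(15:40, 1)
  sizes <- p_groups %||% sample(1:5, sample(2:4, 1), replace = TRUE)
  p <- sum(sizes)
  Z <- matrix(rnorm(n * p), n)
  Z <- scale(Z)
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  colnames(Z) <- paste0("v", seq_len(p))
  groups <- split(colnames(Z), rep(seq_along(sizes), sizes))
  names(groups) <- paste0("g", seq_along(groups))
  beta <- rnorm(p) * rbinom(p, 1, 0.6)
  y <- as.numeric(Z %*% beta + rnorm(n, 0, 0.5))
  y <- (y - mean(y)) / sd(y)
  list(Z = Z, y = y, groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
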