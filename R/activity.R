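#' Locality preserving projection (LPP)
#'
#' Linear dimensionality reduction that preserves a k-nearest-neighbour
#' heat-kernel graph. With affinity `W` (symmetrized kNN graph,
#' `w_ij = exp(-||x_i - x_j||^2 / bandwidth)`), degree `D = diag(rowSums(W))`
#' and Laplacian `L = D - W`, the projection directions `a` solve the
#' generalized eigenproblem `X'LX a = lambda X'DX a`; the `out_dim`
#' eigenvectors with the smallest eigenvalues become the projection matrix,
#' ordered by ascending eigenvalue. A rank-deficient right-hand scatter is
#' regularized by a small ridge on its diagonal (with a warning).
#'
#' @param X numeric matrix (rows = observations), already standardized.
#' @param out_dim embedding dimension.
#' @param knn neighbourhood size of the graph.
#' @param bandwidth heat-kernel bandwidth; default is the median squared
#'   kNN distance.
#' @return An object of class `lpp_projection` with elements `rotation`
#'   (d x out_dim), `eigenvalues`, `knn`, `bandwidth`.
#' @export
fit_lpp <- function(X, out_dim = 3, knn = 10, bandwidth = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= knn) abort("need more observations than knn")
  d2 <- as.matrix(stats::dist(X))^2
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(knn)]))
  knn_d2 <- t(apply(d2, 1, function(r) sort(r)[seq_len(knn)]))
  if (is.null(bandwidth)) {
    bandwidth <- median(knn_d2)
    if (bandwidth < 1e-12) bandwidth <- 1
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, nn[i, ]] <- exp(-d2[i, nn[i, ]] / bandwidth)
  W <- pmax(W, t(W))                      # symmetrize: union of kNN edges
  D <- rowSums(W)
  # X'LX and X'DX without forming L explicitly
  XD <- X * D
  A <- crossprod(X, XD) - crossprod(X, W %*% X)
  A <- (A + t(A)) / 2
  B <- crossprod(X, XD)
  B <- (B + t(B)) / 2
  eps <- 1e-10 * mean(diag(B))
  ch <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(ch)) {
    warn("rank-deficient scatter in LPP; adding ridge regularization")
    ch <- chol(B + diag(1e-6 * mean(diag(B)) + eps, ncol(B)))
  }
  Ci <- backsolve(ch, diag(ncol(B)))      # inv(R), B = R'R
  S <- crossprod(Ci, A %*% Ci)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(e$values)
  take <- ord[seq_len(out_dim)]
  rot <- Ci %*% e$vectors[, take, drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  rownames(rot) <- colnames(X)
  structure(list(rotation = rot, eigenvalues = e$values[take],
                 knn = knn, bandwidth = bandwidth),
            class = "lpp_projection")
}

#' Project new rows with a fitted LPP
#' @param object a [fit_lpp()] result.
#' @param X standardized matrix with the training columns.
#' @param ... unused.
#' @return Embedded matrix (rows x out_dim).
#' @export
predict.lpp_projection <- function(object, X, ...) {
  as.matrix(X) %*% object$rotation
}

#' k-means activity clusters in the embedded space
#'
#' Runs k-means with multiple random restarts and relabels the clusters in
#' descending size so cluster ids are reproducible.
#'
#' @param embedded numeric matrix of embedded rows.
#' @param K number of clusters.
#' @param seed integer seed.
#' @param nstart number of restarts.
#' @return List with `centroids` (K x dim) and `sizes` (training counts).
#' @export
fit_clusters <- function(embedded, K = 4, seed = 1, nstart = 20) {
  embedded <- as.matrix(embedded)
  if (nrow(embedded) < K) abort("fewer rows than clusters")
  set.seed(seed)
  km <- kmeans(embedded, centers = K, nstart = nstart, iter.max = 100)
  ord <- order(km$size, decreasing = TRUE)
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- NULL
  list(centroids = centroids, sizes = as.integer(km$size[ord]))
}

#' Fit the activity cluster model
#'
#' Implements the activity cluster function: the 21 context-sensor window
#' features (ankle accelerometer by default) are standardized, reduced to
#' three dimensions with [fit_lpp()], and partitioned with k-means (K = 4
#' by default, matching walking / running / resting / exercising). For
#' large designs the LPP graph and k-means are fitted on at most
#' `fit_max_rows` evenly spaced training rows; assignment of all rows is
#' exact.
#'
#' @param design a [build_design()] result.
#' @param rows training row indices.
#' @param context context sensor group name.
#' @param K number of clusters.
#' @param out_dim,knn,bandwidth LPP parameters, see [fit_lpp()].
#' @param seed integer seed for k-means restarts.
#' @param fit_max_rows cap on rows used to fit the graph and centroids.
#' @return An object of class `activity_model`.
#' @export
fit_activity <- function(design, rows = seq_len(nrow(design)),
                         context = "ankle_accel", K = 4, out_dim = 3,
                         knn = 10, bandwidth = NULL, seed = 1,
                         fit_max_rows = 3000) {
  groups <- attr(design, "groups")
  if (!context %in% names(groups)) abort(paste0("no context group '", context, "'"))
  cols <- groups[[context]]
  X <- as.matrix(design[rows, cols])
  center <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-10] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  sub <- if (nrow(Z) > fit_max_rows) {
    round(seq(1, nrow(Z), length.out = fit_max_rows))
  } else seq_len(nrow(Z))
  lpp <- fit_lpp(Z[sub, , drop = FALSE], out_dim = out_dim, knn = knn,
                 bandwidth = bandwidth)
  emb <- predict(lpp, Z)
  cl <- fit_clusters(emb[sub, , drop = FALSE], K = K, seed = seed)
  model <- structure(
    list(lpp = lpp, center = center, scale = scl, feature_cols = cols,
         centroids = cl$centroids, K = K, context = context),
    class = "activity_model")
  train_assign <- assign_activity(model, design[rows, ])
  model$sizes <- as.integer(table(factor(train_assign, levels = seq_len(K))))
  model
}

#' Assign rows to activity clusters
#'
#' Nearest-centroid assignment in the embedded space; ties break to the
#' lowest cluster index. A pure function of the stored model.
#'
#' @param model an [fit_activity()] result.
#' @param design design rows carrying the context feature columns.
#' @return Integer cluster indices.
#' @export
assign_activity <- function(model, design) {
  X <- as.matrix(design[, model$feature_cols, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  emb <- predict(model$lpp, Z)
  d2 <- outer(rowSums(emb^2), rep(1, nrow(model$centroids))) -
    2 * emb %*% t(model$centroids) +
    outer(rep(1, nrow(emb)), rowSums(model$centroids^2))
  max.col(-d2, ties.method = "first")
}

#' Fill the cluster column of a design
#'
#' @param design a [build_design()] result.
#' @param model an [fit_activity()] result.
#' @return The design with its `cluster` column filled.
#' @export
assign_clusters <- function(design, model) {
  design$cluster <- assign_activity(model, design)
  design
}

#' Persist / load an activity model as JSON
#' @param model an [fit_activity()] result.
#' @param path JSON path.
#' @return `path` invisibly, or the model for `read_activity_model()`.
#' @export
write_activity_model <- function(model, path) {
  jsonlite::write_json(list(
    rotation = model$lpp$rotation, eigenvalues = model$lpp$eigenvalues,
    knn = model$lpp$knn, bandwidth = model$lpp$bandwidth,
    center = as.list(model$center), scale = as.list(model$scale),
    feature_cols = model$feature_cols, centroids = model$centroids,
    K = model$K, context = model$context, sizes = model$sizes
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_activity_model
#' @export
read_activity_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lpp <- structure(list(rotation = as.matrix(j$rotation),
                        eigenvalues = j$eigenvalues, knn = j$knn,
                        bandwidth = j$bandwidth), class = "lpp_projection")
  rownames(lpp$rotation) <- j$feature_cols
  structure(list(lpp = lpp, center = unlist(j$center), scale = unlist(j$scale),
                 feature_cols = j$feature_cols,
                 centroids = as.matrix(j$centroids), K = j$K,
                 context = j$context, sizes = j$sizes),
            class = "activity_model")
}
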