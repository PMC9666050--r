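# Principal component analysis by eigendecomposition of the 1/n covariance of
# the mean-centred (optionally standardized) training features.

#' Fit a PCA model
#'
#' Centres the columns of `X` (and optionally scales them to unit standard
#' deviation), forms the covariance `C = (1/n) * t(Xc) %*% Xc` and
#' eigendecomposes it. The top `k` eigenvectors (by eigenvalue, descending) are
#' retained as the projection matrix. The `1/n` normalisation (rather than
#' `1/(n-1)`) follows the decentralised-covariance formulation of the method
#' this package implements. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making serialized models
#' reproducible; eigenvalue ties are left in eigendecomposition order.
#'
#' @param X Numeric matrix, rows = observations (at least 2), columns =
#'   features.
#' @param k Number of components to retain, `1 <= k <= min(nrow(X)-1, ncol(X))`.
#' @param standardize If `TRUE`, columns are scaled by their standard deviation
#'   after centring; a zero-variance column is then an error.
#' @return An object of class `"emg_pca"`: list with `mean`, `scale` (or
#'   `NULL`), `components` (`k x n_features`, rows = eigenvectors),
#'   `eigenvalues` (all `ncol(X)` eigenvalues, nonincreasing), `k`.
#' @examples
#' X <- cbind(c(1, -1, 2, -2), 0)
#' pca_fit(X, k = 1)$eigenvalues[1]  # 2.5
#' @export
pca_fit <- function(X, k, standardize = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 rows")
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, p))
    stop("k must be in 1..", min(n - 1L, p))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sc <- NULL
  if (standardize) {
    sc <- apply(Xc, 2L, stats::sd)
    zero <- which(sc <= .Machine$double.eps)
    if (length(zero) > 0L)
      stop("zero-variance column(s) with standardize = TRUE: ",
           paste(if (!is.null(colnames(X))) colnames(X)[zero] else zero,
                 collapse = ", "))
    Xc <- sweep(Xc, 2L, sc, "/")
  }
  C <- crossprod(Xc) / n
  eig <- eigen(C, symmetric = TRUE)  # eigenvalues already nonincreasing
  comps <- t(eig$vectors[, seq_len(k), drop = FALSE])
  # deterministic sign: largest-|loading| entry of each component positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  structure(list(mean = mu, scale = sc, components = comps,
                 eigenvalues = eig$values, k = k,
                 feature_names = colnames(X)),
            class = "emg_pca")
}

#' @export
print.emg_pca <- function(x, ...) {
  p <- length(x$mean)
  explained <- sum(pmax(x$eigenvalues[seq_len(x$k)], 0)) /
    sum(pmax(x$eigenvalues, 0))
  cat(sprintf("PCA model: %d -> %d dimensions (%.1f%% variance retained)%s\n",
              p, x$k, 100 * explained,
              if (is.null(x$scale)) "" else ", standardized"))
  invisible(x)
}

#' Project data into the PCA space
#'
#' Applies the training-fold centring (and scaling, if the model was fitted
#' with `standardize = TRUE`) and projects onto the retained components:
#' `Y = (X - mean) %*% t(P)`.
#'
#' @param model An `"emg_pca"` model.
#' @param X Numeric matrix with the same number of columns the model was
#'   fitted on.
#' @return Numeric matrix `nrow(X) x k`.
#' @export
pca_transform <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop("X has ", ncol(X), " columns; model was fitted on ",
         length(model$mean))
  Xc <- sweep(X, 2L, model$mean)
  if (!is.null(model$scale)) Xc <- sweep(Xc, 2L, model$scale, "/")
  Xc %*% t(model$components)
}

#' Reconstruct from the PCA space
#'
#' Inverse map of [pca_transform()]: `X_hat = Y %*% P [* scale] + mean`. Exact
#' when `k` equals the number of features; otherwise the least-squares
#' rank-`k` approximation.
#'
#' @param model An `"emg_pca"` model.
#' @param Y Score matrix with `k` columns.
#' @return Numeric matrix in the original feature space.
#' @export
pca_inverse <- function(model, Y) {
  Y <- as.matrix(Y)
  if (ncol(Y) != model$k) stop("Y must have k = ", model$k, " columns")
  Xc <- Y %*% model$components
  if (!is.null(model$scale)) Xc <- sweep(Xc, 2L, model$scale, "*")
  sweep(Xc, 2L, model$mean, "+")
}
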