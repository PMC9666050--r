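# The three classifiers behind one train/predict contract: hand-rolled
# Euclidean-distance KNN with deterministic tie-breaking, Gaussian-kernel SVM
# (e1071/libsvm, one-vs-one multiclass), and bagged rpart decision trees.

# run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.class_order <- function(y) {
  u <- unique(y)
  canon <- movement_classes()
  if (all(u %in% canon)) canon[canon %in% u] else sort(u)
}

#' Train a hand-movement classifier
#'
#' One contract over the three supported classifiers:
#' \describe{
#'   \item{knn}{K-nearest neighbours, Euclidean distance, majority vote.
#'     Vote ties are broken by the smallest summed distance among the tied
#'     classes' neighbours, then by class order. `params$k` (default 5).}
#'   \item{svm}{Support vector machine with Gaussian (radial-basis) kernel,
#'     one-vs-one multiclass voting. `params$cost` (default 1) and
#'     `params$gamma` (default `1 / (n_features * mean column variance)`).}
#'   \item{bagging}{Bootstrap-aggregated decision trees (fully grown rpart
#'     trees), plurality vote. `params$n_estimators` (default 100). Bootstrap
#'     resampling is drawn from `seed`, so training is reproducible.}
#' }
#' For the distance-based classifiers (knn, svm) the feature columns are
#' z-scored internally using training statistics (`params$scale = FALSE`
#' disables this); trees are scale-invariant and are left unscaled.
#'
#' @param kind `"knn"`, `"svm"` or `"bagging"`.
#' @param X Numeric feature matrix (rows = training windows).
#' @param y Class labels, one per row; at least two distinct classes.
#' @param params Named list of hyperparameters, see above.
#' @param seed Integer seed for the bagging bootstrap (ignored by knn/svm).
#' @return An object of class `"emg_classifier"` with a [predict()] method.
#' @export
train_classifier <- function(kind = c("knn", "svm", "bagging"), X, y,
                             params = list(), seed = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  classes <- .class_order(y)
  if (length(classes) < 2L) stop("training labels contain a single class")
  scale_cols <- isTRUE(params$scale %||% (kind %in% c("knn", "svm")))
  ctr <- scl <- NULL
  if (scale_cols) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl <= .Machine$double.eps] <- 1
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  }
  state <- switch(kind,
    knn = {
      k <- as.integer(params$k %||% 5L)
      if (k < 1L) stop("knn k must be positive")
      if (k > nrow(X)) stop("knn k (", k, ") exceeds training size (", nrow(X), ")")
      list(k = k, X = X, y = y)
    },
    svm = {
      cost <- params$cost %||% 1
      gamma <- params$gamma %||% {
        v <- mean(apply(X, 2L, stats::var))
        if (v <= 0) 1 / ncol(X) else 1 / (ncol(X) * v)
      }
      fit <- e1071::svm(X, factor(y, levels = classes), kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      list(fit = fit, cost = cost, gamma = gamma)
    },
    bagging = {
      m <- as.integer(params$n_estimators %||% 100L)
      if (m < 1L) stop("n_estimators must be positive")
      df <- data.frame(.y = factor(y, levels = classes), X, check.names = FALSE)
      trees <- .with_seed(seed, function() {
        lapply(seq_len(m), function(i) {
          idx <- sample.int(nrow(df), replace = TRUE)
          rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                       method = "class",
                       control = rpart::rpart.control(cp = 0, minsplit = 2L,
                                                      xval = 0L))
        })
      })
      list(trees = trees, m = m)
    })
  structure(list(kind = kind, classes = classes, state = state,
                 center = ctr, scale = scl, n_features = ncol(X),
                 col_names = colnames(X), seed = seed),
            class = "emg_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.emg_classifier <- function(x, ...) {
  extra <- switch(x$kind,
    knn = sprintf("k = %d", x$state$k),
    svm = sprintf("cost = %g, gamma = %.4g", x$state$cost, x$state$gamma),
    bagging = sprintf("%d trees", x$state$m))
  cat(sprintf("%s classifier (%s), %d features, classes: %s\n",
              x$kind, extra, x$n_features, paste(x$classes, collapse = " ")))
  invisible(x)
}

# KNN prediction with the deterministic tie rules: majority vote over the K
# nearest training rows; vote ties broken by smallest summed distance of the
# tied class's neighbours, then by class order.
.knn_predict <- function(state, classes, Q) {
  if (nrow(Q) == 0L) return(character(0))
  Tr <- state$X
  k <- state$k
  # squared Euclidean distances, queries x training
  d2 <- outer(rowSums(Q^2), rowSums(Tr^2), "+") - 2 * Q %*% t(Tr)
  d2[d2 < 0] <- 0
  vapply(seq_len(nrow(Q)), function(i) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    lab <- state$y[ord]
    dist <- sqrt(d2[i, ord])
    counts <- table(factor(lab, levels = classes))
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(cl) sum(dist[lab == cl]), numeric(1L))
      top <- top[sums == min(sums)]  # still ordered by class order
    }
    top[1L]
  }, character(1L))
}

#' Predict hand-movement labels
#'
#' @param object An `"emg_classifier"` from [train_classifier()].
#' @param newdata Numeric matrix with the same columns as the training data.
#' @param ... Unused.
#' @return Character vector of predicted class labels (possibly empty).
#' @export
predict.emg_classifier <- function(object, newdata, ...) {
  Q <- as.matrix(newdata)
  if (ncol(Q) != object$n_features)
    stop("newdata has ", ncol(Q), " columns; classifier was trained on ",
         object$n_features)
  if (!is.null(object$center))
    Q <- sweep(sweep(Q, 2L, object$center), 2L, object$scale, "/")
  if (nrow(Q) == 0L) return(character(0))
  colnames(Q) <- object$col_names
  switch(object$kind,
    knn = .knn_predict(object$state, object$classes, Q),
    svm = as.character(stats::predict(object$state$fit, Q)),
    bagging = {
      df <- data.frame(Q, check.names = FALSE)
      votes <- matrix(0L, nrow(Q), length(object$classes))
      for (tree in object$state$trees) {
        pred <- stats::predict(tree, df, type = "class")
        m <- match(as.character(pred), object$classes)
        votes[cbind(seq_len(nrow(Q)), m)] <- votes[cbind(seq_len(nrow(Q)), m)] + 1L
      }
      object$classes[apply(votes, 1L, which.max)]
    })
}
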