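# The fitted-pipeline interface: semg_fit() trains the complete
# window -> wavelet packet features -> PCA -> classifier chain on labelled
# recordings and returns one model object usable on new recordings.

#' Fit the sEMG hand-movement recognition pipeline
#'
#' Trains the full chain on labelled recordings: segmentation into fixed
#' windows, wavelet packet feature extraction (MAV/RMS/MNF/MDF per terminal
#' sub-band per channel), PCA reduction, and one of the three classifiers.
#' The defaults are the configuration found to perform best in the study this
#' package operationalises: dmey basis, level 3, 400-sample windows,
#' 30 retained components, KNN.
#'
#' @param recordings List of labelled `"emg_recording"` objects.
#' @param basis,level Wavelet packet basis and depth.
#' @param window_length,overlap Segmentation parameters.
#' @param k_pca Retained PCA dimension; `NULL` skips the reduction.
#' @param standardize Standardize features in the PCA step.
#' @param classifier `"knn"`, `"svm"` or `"bagging"`.
#' @param params Classifier hyperparameters ([train_classifier()]).
#' @param spectrum_on Spectral-feature mode ([extract_features()]).
#' @param seed Seed (bagging bootstrap).
#' @return An object of class `"semg_model"` with `print`, `summary`,
#'   `predict` and `plot` methods.
#' @examples
#' recs <- generate_recordings(synth_spec(n_trials_per_class = 6, delta = 2),
#'                             seed = 7)
#' fit <- semg_fit(recs, k_pca = 10, params = list(k = 3))
#' fit
#' @export
semg_fit <- function(recordings, basis = "dmey", level = 3L,
                     window_length = 400L, overlap = 0, k_pca = 30L,
                     standardize = TRUE, classifier = "knn", params = list(),
                     spectrum_on = "coefficients", seed = 42L) {
  windows <- segment_recordings(recordings, window_length, overlap)
  fm <- feature_matrix(windows, basis = basis, level = level,
                       spectrum_on = spectrum_on)
  X <- fm$values
  pca <- NULL
  if (!is.null(k_pca)) {
    pca <- pca_fit(X, k = k_pca, standardize = standardize)
    X <- pca_transform(pca, X)
  }
  clf <- train_classifier(classifier, X, fm$labels, params = params,
                          seed = seed)
  structure(list(pca = pca, classifier = clf,
                 config = list(basis = basis, level = level,
                               window_length = window_length,
                               overlap = overlap, k_pca = k_pca,
                               standardize = standardize,
                               classifier = classifier, params = params,
                               spectrum_on = spectrum_on, rate = windows[[1L]]$rate),
                 classes = clf$classes, n_windows = nrow(fm$values),
                 label_counts = table(fm$labels), seed = seed),
            class = "semg_model")
}

#' @export
print.semg_model <- function(x, ...) {
  cfg <- x$config
  cat("sEMG hand-movement recognition model\n")
  cat(sprintf("  features : %s wavelet packets, level %d, %d-sample windows (overlap %g)\n",
              cfg$basis, cfg$level, cfg$window_length, cfg$overlap))
  cat(sprintf("  reduction: %s\n",
              if (is.null(x$pca)) "none"
              else sprintf("PCA to %d of %d dimensions", x$pca$k,
                           length(x$pca$mean))))
  cat(sprintf("  trained  : %s on %d windows, classes %s\n",
              cfg$classifier, x$n_windows, paste(x$classes, collapse = " ")))
  invisible(x)
}

#' @export
summary.semg_model <- function(object, ...) {
  print(object)
  if (!is.null(object$pca)) {
    ev <- pmax(object$pca$eigenvalues, 0)
    cum <- cumsum(ev) / sum(ev)
    cat(sprintf("  PCA variance retained by k = %d components: %.1f%%\n",
                object$pca$k, 100 * cum[object$pca$k]))
  }
  cat("  training windows per class:\n")
  print(object$label_counts)
  invisible(object)
}

#' Predict movement labels for new recordings
#'
#' New recordings are segmented and featurised exactly as during training
#' (same window length, basis, level and PCA projection — all statistics come
#' from the training data). Predictions are per window; `type = "trial"`
#' aggregates them to one label per recording by majority vote (ties broken by
#' class order).
#'
#' @param object A fitted `"semg_model"`.
#' @param newdata A list of `"emg_recording"` objects, a single recording, a
#'   list of `"emg_window"` objects, or a ready feature matrix.
#' @param type `"window"` (default) or `"trial"`.
#' @param ... Unused.
#' @return For `type = "window"` a data.frame with `subject`, `trial`,
#'   `start_index` and `predicted` (plus `label` when the inputs carry one);
#'   for `type = "trial"` one row per recording. For a bare feature matrix,
#'   a character vector.
#' @export
predict.semg_model <- function(object, newdata, type = c("window", "trial"),
                               ...) {
  type <- match.arg(type)
  cfg <- object$config
  if (is.matrix(newdata)) {
    X <- newdata
    if (!is.null(object$pca) && ncol(X) == length(object$pca$mean))
      X <- pca_transform(object$pca, X)
    return(predict(object$classifier, X))
  }
  if (inherits(newdata, "emg_recording")) newdata <- list(newdata)
  windows <- if (length(newdata) > 0L && inherits(newdata[[1L]], "emg_window"))
    newdata
  else segment_recordings(newdata, cfg$window_length, cfg$overlap)
  fm <- feature_matrix(windows, basis = cfg$basis, level = cfg$level,
                       spectrum_on = cfg$spectrum_on)
  X <- fm$values
  if (!is.null(object$pca)) X <- pca_transform(object$pca, X)
  pred <- predict(object$classifier, X)
  out <- data.frame(subject = fm$subjects, trial = fm$trials,
                    start_index = fm$start_indices, label = fm$labels,
                    predicted = pred)
  if (type == "window") return(out)
  agg <- lapply(split(out, paste(out$subject, out$trial, out$label, sep = "|")),
                function(d) {
    votes <- table(factor(d$predicted, levels = object$classes))
    data.frame(subject = d$subject[1L], trial = d$trial[1L],
               label = d$label[1L],
               predicted = names(votes)[which.max(votes)])
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Scree plot of the fitted PCA
#'
#' Plots the eigenvalue spectrum of the model's PCA step with the retained
#' dimension marked, and the cumulative variance curve.
#'
#' @param x A fitted `"semg_model"` (with a PCA step).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.semg_model <- function(x, ...) {
  if (is.null(x$pca)) stop("model has no PCA step to plot")
  ev <- pmax(x$pca$eigenvalues, 0)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(ev), ev, type = "h", xlab = "component",
                 ylab = "eigenvalue", main = "PCA spectrum", ...)
  graphics::abline(v = x$pca$k + 0.5, lty = 2)
  graphics::plot(seq_along(ev), cumsum(ev) / sum(ev), type = "l",
                 xlab = "components", ylab = "cumulative variance",
                 ylim = c(0, 1), main = "variance retained")
  graphics::abline(v = x$pca$k, lty = 2)
  invisible(x)
}
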