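# Cross-validated evaluation: confusion matrices, one-vs-rest per-class
# metrics, group-aware stratified k-fold validation, and the Kruskal-Wallis
# feature screen.

#' Confusion matrix
#'
#' @param true,predicted Label vectors of equal length.
#' @param classes Ordered class labels; defaults to the classes present.
#' @return An object of class `"emg_confusion"`: integer matrix, rows = true
#'   class, columns = predicted class.
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  if (length(true) != length(predicted)) stop("length mismatch")
  if (is.null(classes)) classes <- .class_order(c(true, predicted))
  m <- table(factor(true, levels = classes),
             factor(predicted, levels = classes))
  cm <- matrix(as.integer(m), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  structure(cm, class = c("emg_confusion", "matrix"))
}

#' @export
print.emg_confusion <- function(x, ...) {
  cat("confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class metrics from a confusion matrix
#'
#' For each class, the one-vs-rest counts TP, TN, FP, FN give
#' `accuracy = (TP+TN)/(TP+TN+FN+FP)`, `recall = TP/(TP+FN)`,
#' `precision = TP/(TP+FP)` and `F1 = 2*recall*precision/(recall+precision)`.
#' A class with no true or no predicted instances yields 0 for the undefined
#' ratios, with a warning.
#'
#' @param cm A confusion matrix (rows = true, columns = predicted).
#' @return A data.frame with columns `class`, `TP`, `TN`, `FP`, `FN`,
#'   `accuracy`, `recall`, `precision`, `F1`, plus attribute
#'   `overall_accuracy` (trace over total).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    if (tp + fn == 0L)
      warning("class ", classes[i], " has no true instances; recall set to 0")
    recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
    precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
    f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
    data.frame(class = classes[i], TP = tp, TN = tn, FP = fp, FN = fn,
               accuracy = (tp + tn) / total, recall = recall,
               precision = precision, F1 = f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_accuracy") <- sum(diag(cm)) / total
  out
}

# ---------------------------------------------------------------------------
# cross-validation machinery

# stratified group k-fold: all windows of one (subject, class, trial) group
# land in the same fold; within each class, groups are shuffled (seeded) and
# dealt round-robin so folds are class-balanced
.assign_folds <- function(group_ids, group_labels, n_folds, seed) {
  groups <- !duplicated(group_ids)
  gid <- group_ids[groups]
  glab <- group_labels[groups]
  fold_of <- integer(length(gid))
  names(fold_of) <- gid
  .with_seed(seed, function() {
    for (cl in unique(glab)) {
      idx <- which(glab == cl)
      if (length(idx) < n_folds)
        stop("class ", cl, " has ", length(idx), " trials; need at least ",
             n_folds, " for ", n_folds, "-fold grouped cross-validation")
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <<- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold_of
}

# add seeded white measurement noise to the raw samples of every window
.perturb_windows <- function(windows, sd, seed) {
  .with_seed(seed, function() {
    lapply(windows, function(w) {
      w$samples <- w$samples + matrix(stats::rnorm(length(w$samples), sd = sd),
                                      nrow(w$samples))
      w
    })
  })
}

# evaluate one pool of recordings (one subject, or all pooled): returns the
# summed confusion and per-fold accuracies
.cv_pool <- function(recordings, basis, level, window_length, overlap, k_pca,
                     standardize, classifier, params, n_folds, seed,
                     noise_level, reference_magnitude, spectrum_on) {
  windows <- segment_recordings(recordings, window_length, overlap)
  fm <- feature_matrix(windows, basis = basis, level = level,
                       spectrum_on = spectrum_on)
  test_values <- fm$values
  if (noise_level > 0) {
    noisy <- .perturb_windows(windows, noise_level * reference_magnitude,
                              seed = seed + 211L)
    test_values <- feature_matrix(noisy, basis = basis, level = level,
                                  spectrum_on = spectrum_on)$values
  }
  gids <- paste(fm$subjects, fm$labels, fm$trials, sep = "|")
  fold_of <- .assign_folds(gids, fm$labels, n_folds, seed)
  folds <- fold_of[gids]
  classes <- .class_order(fm$labels)
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    te <- !tr
    Xtr <- fm$values[tr, , drop = FALSE]
    Xte <- test_values[te, , drop = FALSE]
    if (!is.null(k_pca)) {
      pca <- pca_fit(Xtr, k = k_pca, standardize = standardize)
      Xtr <- pca_transform(pca, Xtr)
      Xte <- pca_transform(pca, Xte)
    }
    clf <- train_classifier(classifier, Xtr, fm$labels[tr], params = params,
                            seed = seed + 97L * f)
    pred <- predict(clf, Xte)
    cmf <- confusion_matrix(fm$labels[te], pred, classes)
    cm <- cm + unclass(cmf)
    acc[f] <- sum(diag(unclass(cmf))) / sum(cmf)
  }
  list(confusion = cm, fold_accuracy = acc, fold_assignments = fold_of,
       n_windows = length(windows))
}

#' Grouped, stratified cross-validated evaluation of the full pipeline
#'
#' Segments the recordings into windows, extracts wavelet packet features,
#' then runs stratified k-fold cross-validation grouped by trial: all windows
#' of one trial stay in the same fold, so no window-level information leaks
#' between training and testing. Within each fold, PCA (and its optional
#' standardisation) and the classifier are fitted on the training windows
#' only. With `noise_level > 0`, classifiers are trained on clean windows and
#' evaluated on windows perturbed with zero-mean Gaussian noise of standard
#' deviation `noise_level * reference_magnitude` (features re-extracted from
#' the perturbed signals).
#'
#' @param recordings List of `"emg_recording"` objects.
#' @param basis,level Wavelet packet basis and depth (defaults dmey, 3).
#' @param window_length,overlap Segmentation parameters (defaults 400, 0).
#' @param k_pca Retained PCA dimension (default 30); `NULL` skips PCA.
#' @param standardize Standardize features in the PCA step (default `TRUE`:
#'   the amplitude features (signal units) and spectral features (Hz) live on
#'   scales about six orders of magnitude apart, and an unstandardized
#'   covariance is dominated entirely by the Hz-scale block).
#' @param classifier `"knn"`, `"svm"` or `"bagging"`.
#' @param params Classifier hyperparameters, see [train_classifier()].
#' @param n_folds Number of folds (default 5).
#' @param seed Root seed for fold shuffling, bagging and noise (default 42).
#' @param subject_mode `"per_subject"` (default): each subject is evaluated
#'   with its own models and accuracies are averaged across subjects;
#'   `"pooled"`: one model pool over all subjects.
#' @param noise_level Test-time noise level (0 = clean).
#' @param reference_magnitude Scale of the noise levels in signal units
#'   (default 1, i.e. levels are absolute).
#' @param spectrum_on Passed to [feature_matrix()].
#' @return An object of class `"emg_evaluation"`: list with `confusion`
#'   (summed over folds and subjects), `per_class` metrics, `overall_accuracy`
#'   (mean of per-fold accuracies, averaged over subjects), `accuracy_sd`,
#'   `accuracy_by_fold`, `window_accuracy` (trace/total of the summed
#'   confusion), `fold_assignments`, `config`, `seed`.
#' @export
cross_validate <- function(recordings, basis = "dmey", level = 3L,
                           window_length = 400L, overlap = 0, k_pca = 30L,
                           standardize = TRUE, classifier = "knn",
                           params = list(), n_folds = 5L, seed = 42L,
                           subject_mode = c("per_subject", "pooled"),
                           noise_level = 0, reference_magnitude = 1,
                           spectrum_on = "coefficients") {
  subject_mode <- match.arg(subject_mode)
  subjects <- vapply(recordings, function(r) as.character(r$subject),
                     character(1L))
  pools <- if (subject_mode == "per_subject") {
    lapply(unique(subjects), function(s) recordings[subjects == s])
  } else list(recordings)
  res <- lapply(seq_along(pools), function(i)
    .cv_pool(pools[[i]], basis, level, window_length, overlap, k_pca,
             standardize, classifier, params, n_folds, seed + 1000L * (i - 1L),
             noise_level, reference_magnitude, spectrum_on))
  cm <- Reduce(`+`, lapply(res, `[[`, "confusion"))
  fold_acc <- do.call(rbind, lapply(res, `[[`, "fold_accuracy"))
  per_class <- suppressWarnings(metrics_from_confusion(cm))
  fold_assignments <- do.call(c, lapply(res, `[[`, "fold_assignments"))
  config <- list(basis = basis, level = level, window_length = window_length,
                 overlap = overlap, k_pca = k_pca, standardize = standardize,
                 classifier = classifier, params = params, n_folds = n_folds,
                 subject_mode = subject_mode, noise_level = noise_level,
                 reference_magnitude = reference_magnitude,
                 spectrum_on = spectrum_on)
  structure(list(confusion = structure(cm, class = c("emg_confusion", "matrix")),
                 per_class = per_class,
                 overall_accuracy = mean(fold_acc),
                 accuracy_sd = stats::sd(as.vector(fold_acc)),
                 accuracy_by_fold = fold_acc,
                 window_accuracy = attr(per_class, "overall_accuracy"),
                 n_windows = sum(vapply(res, `[[`, numeric(1L), "n_windows")),
                 fold_assignments = fold_assignments,
                 config = config, seed = seed),
            class = "emg_evaluation")
}

#' @export
print.emg_evaluation <- function(x, ...) {
  cat(sprintf("cross-validated evaluation: %s + %s, basis %s, window %d\n",
              x$config$classifier,
              if (is.null(x$config$k_pca)) "no PCA"
              else paste0("PCA-", x$config$k_pca),
              x$config$basis, x$config$window_length))
  cat(sprintf("  overall accuracy %.4f (sd %.4f over %d folds), %d windows\n",
              x$overall_accuracy, x$accuracy_sd, x$config$n_folds, x$n_windows))
  print(x$confusion)
  invisible(x)
}

#' @export
summary.emg_evaluation <- function(object, ...) {
  print(object)
  cat("\nper-class metrics (one-vs-rest):\n")
  print(object$per_class, row.names = FALSE)
  invisible(object$per_class)
}

#' Kruskal-Wallis feature screen
#'
#' Runs a tie-corrected Kruskal-Wallis rank test (chi-squared approximation,
#' `k - 1` degrees of freedom) of each feature column against the class
#' labels. Constant columns get `H = 0`, `p = 1` with a warning.
#'
#' @param X Numeric matrix (rows = windows, columns = features, e.g. PCA
#'   scores).
#' @param labels Class label per row; at least two classes with two rows each.
#' @return data.frame with columns `feature`, `H`, `p`.
#' @export
kruskal_wallis_screen <- function(X, labels) {
  X <- as.matrix(X)
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least two classes")
  if (any(table(g) < 2L)) stop("need at least two rows per class")
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("PC", seq_len(ncol(X)))
  rows <- lapply(seq_len(ncol(X)), function(j) {
    col <- X[, j]
    if (stats::sd(col) <= .Machine$double.eps) {
      warning("feature ", nm[j], " is constant; H = 0, p = 1")
      return(data.frame(feature = nm[j], H = 0, p = 1))
    }
    kt <- stats::kruskal.test(col, g)
    data.frame(feature = nm[j], H = unname(kt$statistic), p = kt$p.value)
  })
  do.call(rbind, rows)
}
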