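# Experiment sweeps mirroring the four evaluation studies: wavelet basis,
# retained PCA dimension, test-time noise level, and window size. Each sweep
# returns one accuracy table with the swept parameter in rows and one column
# per classifier.

.run_sweep <- function(values, value_name, classifiers, cell_fun) {
  out <- data.frame(values)
  names(out) <- value_name
  for (clf in classifiers)
    out[[clf]] <- vapply(seq_along(values), function(i) cell_fun(values[i], clf),
                         numeric(1L))
  attr(out, "classifiers") <- classifiers
  out
}

#' Wavelet-basis sweep
#'
#' Cross-validated accuracy for every combination of wavelet packet basis and
#' classifier, at a fixed pipeline configuration.
#'
#' @param recordings List of `"emg_recording"` objects.
#' @param bases Bases to compare (default all five).
#' @param classifiers Classifiers to compare (default all three).
#' @param ... Fixed configuration passed to [cross_validate()] (e.g. `level`,
#'   `window_length`, `k_pca`, `n_folds`, `seed`).
#' @return data.frame: one row per basis, one accuracy column per classifier.
#' @export
sweep_basis <- function(recordings, bases = wavelet_basis_names(),
                        classifiers = c("knn", "svm", "bagging"), ...) {
  .run_sweep(bases, "basis", classifiers, function(b, clf)
    cross_validate(recordings, basis = b, classifier = clf, ...)$overall_accuracy)
}

#' PCA-dimension sweep
#'
#' @param dims Retained dimensions to compare (default 10, 20, 30, 40, 50).
#' @inheritParams sweep_basis
#' @return data.frame: one row per dimension, one accuracy column per
#'   classifier.
#' @export
sweep_dimension <- function(recordings, dims = c(10L, 20L, 30L, 40L, 50L),
                            classifiers = c("knn", "svm", "bagging"), ...) {
  .run_sweep(dims, "dimension", classifiers, function(d, clf)
    cross_validate(recordings, k_pca = d, classifier = clf, ...)$overall_accuracy)
}

#' Noise-level sweep (train clean, test noisy)
#'
#' Classifiers are trained on clean windows; test windows are perturbed with
#' zero-mean Gaussian noise of standard deviation
#' `level * reference_magnitude` and features re-extracted before prediction.
#'
#' @param levels Noise levels (default 1e-2, 1e-1, 3e-1, 5e-1, 8e-1).
#' @param reference_magnitude Signal-unit scale of the levels (default 1,
#'   absolute units; set to the data magnitude for relative levels).
#' @inheritParams sweep_basis
#' @return data.frame: one row per noise level, one accuracy column per
#'   classifier.
#' @export
sweep_noise <- function(recordings, levels = c(1e-2, 1e-1, 3e-1, 5e-1, 8e-1),
                        reference_magnitude = 1,
                        classifiers = c("knn", "svm", "bagging"), ...) {
  .run_sweep(levels, "noise_level", classifiers, function(lv, clf)
    cross_validate(recordings, noise_level = lv,
                   reference_magnitude = reference_magnitude,
                   classifier = clf, ...)$overall_accuracy)
}

#' Window-size sweep
#'
#' @param sizes Window lengths in samples (default 200, 250, 300, 350, 400).
#' @inheritParams sweep_basis
#' @return data.frame: one row per window size, one accuracy column per
#'   classifier.
#' @export
sweep_window <- function(recordings, sizes = c(200L, 250L, 300L, 350L, 400L),
                         classifiers = c("knn", "svm", "bagging"), ...) {
  .run_sweep(sizes, "window_length", classifiers, function(sz, clf)
    cross_validate(recordings, window_length = sz,
                   classifier = clf, ...)$overall_accuracy)
}
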