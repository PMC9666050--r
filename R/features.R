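# Time- and frequency-domain features of sEMG sub-band signals: MAV, RMS and
# the spectral moments MNF (mean frequency) and MDF (median frequency).

#' Mean absolute value
#'
#' `MAV = (1/N) * sum(|x_i|)`, an amplitude/energy feature of an sEMG window.
#'
#' @param x Numeric vector (non-empty).
#' @return Scalar MAV.
#' @export
mav <- function(x) {
  if (length(x) == 0L) stop("empty sequence")
  mean(abs(x))
}

#' Root mean square
#'
#' `RMS = sqrt((1/N) * sum(x_i^2))`, the quadratic mean amplitude.
#'
#' @param x Numeric vector (non-empty).
#' @return Scalar RMS.
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop("empty sequence")
  sqrt(mean(x^2))
}

#' One-sided periodogram power spectrum
#'
#' Unwindowed, non-detrended periodogram: `P_j = |DFT(x)_j|^2` for
#' `j = 0..floor(N/2)`, with bin frequencies `f_j = j * rate / N`. This is the
#' simplest deterministic estimator and is exact for on-bin sinusoids, which
#' makes the spectral features verifiable in closed form.
#'
#' @param x Numeric vector, length at least 2.
#' @param rate Sampling rate in Hz.
#' @return An object of class `"emg_spectrum"`: list with `freqs`, `power`,
#'   `rate`, `n` (signal length).
#' @export
power_spectrum <- function(x, rate) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples for a spectrum")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  d <- stats::fft(x)
  m <- n %/% 2L
  j <- 0:m
  structure(list(freqs = j * rate / n, power = Mod(d[j + 1L])^2,
                 rate = rate, n = n),
            class = "emg_spectrum")
}

#' @export
print.emg_spectrum <- function(x, ...) {
  cat(sprintf("one-sided periodogram: %d bins over [0, %g] Hz\n",
              length(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Mean frequency of a power spectrum
#'
#' The spectral centroid `MNF = sum(f_j * P_j) / sum(P_j)`. A zero-power
#' spectrum yields 0 with a warning.
#'
#' @param s An `"emg_spectrum"` (or a list with `freqs` and `power`).
#' @return Mean frequency in Hz.
#' @export
mnf <- function(s) {
  p <- s$power
  total <- sum(p)
  if (total <= 0) {
    warning("zero total spectral power; MNF set to 0")
    return(0)
  }
  sum(s$freqs * p) / total
}

#' Median frequency of a power spectrum
#'
#' The frequency of the first bin at which the cumulative power reaches half
#' the total power (smallest-index tie rule, no interpolation). A zero-power
#' spectrum yields 0 with a warning.
#'
#' @param s An `"emg_spectrum"` (or a list with `freqs` and `power`).
#' @return Median frequency in Hz.
#' @export
mdf <- function(s) {
  p <- s$power
  total <- sum(p)
  if (total <= 0) {
    warning("zero total spectral power; MDF set to 0")
    return(0)
  }
  j <- which(cumsum(p) >= total / 2)[1L]
  s$freqs[j]
}

.feature_kinds <- c("MAV", "RMS", "MNF", "MDF")

#' Feature names in canonical column order
#'
#' Channel-major, then band, then feature kind:
#' `ch1_band1_MAV, ch1_band1_RMS, ..., ch2_band8_MDF`. This order is frozen —
#' PCA models and trained classifiers depend on it.
#'
#' @param n_channels Number of channels.
#' @param level Wavelet packet decomposition level (bands = `2^level`).
#' @return Character vector of length `n_channels * 2^level * 4`.
#' @export
feature_names <- function(n_channels = 2L, level = 3L) {
  nb <- 2L^level
  as.vector(vapply(seq_len(n_channels), function(ch)
    vapply(seq_len(nb), function(b)
      paste0("ch", ch, "_band", b, "_", .feature_kinds),
      character(4L)),
    character(4L * nb)))
}

#' Extract the per-window feature vector
#'
#' For each channel of the window, performs a wavelet packet decomposition and
#' computes MAV, RMS, MNF and MDF on every terminal sub-band. MNF and MDF are
#' computed on the sub-band coefficient sequence, whose effective sampling rate
#' is `rate / 2^level` (the sequence is decimated by `2^level`); with
#' `spectrum_on = "reconstruction"` they are computed instead on the
#' band-limited signal reconstructed from that sub-band alone, at the original
#' rate.
#'
#' @param w An `"emg_window"` (or any list with a `samples` matrix and `rate`).
#' @param basis Wavelet basis name.
#' @param level Decomposition level.
#' @param mode Boundary extension mode passed to [wp_decompose()].
#' @param spectrum_on `"coefficients"` (default) or `"reconstruction"`.
#' @return Named numeric vector of length `n_channels * 2^level * 4`, in
#'   [feature_names()] order.
#' @export
extract_features <- function(w, basis = "dmey", level = 3L,
                             mode = "periodic",
                             spectrum_on = c("coefficients", "reconstruction")) {
  spectrum_on <- match.arg(spectrum_on)
  x <- w$samples
  nch <- ncol(x)
  nb <- 2L^level
  out <- numeric(nch * nb * 4L)
  pos <- 0L
  for (ch in seq_len(nch)) {
    s <- wp_decompose(x[, ch], basis = basis, level = level, mode = mode)
    for (b in seq_len(nb)) {
      cb <- s$coeffs[[b]]
      if (spectrum_on == "coefficients") {
        seq_for_spec <- cb
        eff_rate <- w$rate / nb
      } else {
        lone <- s
        lone$coeffs <- lapply(seq_len(nb), function(i)
          if (i == b) cb else numeric(length(cb)))
        seq_for_spec <- wp_reconstruct(lone)
        eff_rate <- w$rate
      }
      spec <- power_spectrum(seq_for_spec, eff_rate)
      zero <- sum(spec$power) <= 0
      out[pos + 1L] <- mav(cb)
      out[pos + 2L] <- rms(cb)
      out[pos + 3L] <- if (zero) 0 else mnf(spec)
      out[pos + 4L] <- if (zero) 0 else mdf(spec)
      if (zero) warning("zero-power sub-band ", b, " in channel ", ch,
                        "; MNF/MDF set to 0")
      pos <- pos + 4L
    }
  }
  names(out) <- feature_names(nch, level)
  out
}

#' Build the feature matrix of a window set
#'
#' Applies [extract_features()] to every window and stacks the results into a
#' matrix with one row per window, carrying labels and (subject, trial) group
#' keys. For the default two-channel, level-3 setting the matrix has
#' `2 * 8 * 4 = 64` columns.
#'
#' @param windows List of `"emg_window"` objects (see [segment_windows()]).
#' @inheritParams extract_features
#' @return An object of class `"emg_features"`: list with `values` (numeric
#'   matrix), `labels` (character), `subjects`, `trials`, `start_indices`,
#'   `basis`, `level`.
#' @export
feature_matrix <- function(windows, basis = "dmey", level = 3L,
                           mode = "periodic",
                           spectrum_on = "coefficients") {
  if (length(windows) == 0L) stop("no windows supplied")
  rows <- lapply(windows, extract_features, basis = basis, level = level,
                 mode = mode, spectrum_on = spectrum_on)
  values <- do.call(rbind, rows)
  structure(list(
    values = values,
    labels = vapply(windows, function(w) w$label, character(1L)),
    subjects = vapply(windows, function(w) as.character(w$subject), character(1L)),
    trials = vapply(windows, function(w) w$trial, integer(1L)),
    start_indices = vapply(windows, function(w) w$start_index, integer(1L)),
    basis = basis, level = level),
    class = "emg_features")
}

#' @export
print.emg_features <- function(x, ...) {
  cat(sprintf("sEMG feature matrix: %d windows x %d features (basis %s, level %d)\n",
              nrow(x$values), ncol(x$values), x$basis, x$level))
  cat("  classes:", paste(names(table(x$labels)), table(x$labels),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' The CSV has columns `label`, `subject`, `trial`, `start_index`, then one
#' column per feature in [feature_names()] order.
#'
#' @param fm An `"emg_features"` object.
#' @param path Output path.
#' @return `path` invisibly (writer); an `"emg_features"` (reader).
#' @export
write_features_csv <- function(fm, path) {
  df <- data.frame(label = fm$labels, subject = fm$subjects,
                   trial = fm$trials, start_index = fm$start_indices,
                   fm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @param basis,level Metadata recorded in the returned object (the CSV itself
#'   is agnostic).
#' @export
read_features_csv <- function(path, basis = "dmey", level = 3L) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("label", "subject", "trial", "start_index")
  vals <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  structure(list(values = vals, labels = as.character(df$label),
                 subjects = as.character(df$subject),
                 trials = as.integer(df$trial),
                 start_indices = as.integer(df$start_index),
                 basis = basis, level = level),
            class = "emg_features")
}
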