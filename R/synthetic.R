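# Seeded synthetic sEMG generator. Classes differ by their power profile over
# the eight level-3 frequency bands of [0, rate/2] and by their inter-channel
# amplitude ratio; the separation dial `delta` scales both differences, with
# delta = 0 making all six classes generatively identical.

# base spectral profile over the 8 bands: EMG-like, energy concentrated in the
# low/mid bands and decaying with frequency
.base_band_weights <- c(1, 0.8, 0.6, 0.45, 0.35, 0.25, 0.18, 0.12)

# two boosted bands per class; adjacent classes share one band so classes are
# separable but not trivially so (support patterns at Hamming distance 2)
.class_band_support <- list(CY = c(1L, 2L), TI = c(2L, 3L), HO = c(3L, 4L),
                            PA = c(4L, 5L), SP = c(5L, 6L), LA = c(6L, 7L))

# per-class channel asymmetry directions
.class_channel_dir <- c(CY = -1, TI = -0.6, HO = -0.2, PA = 0.2, SP = 0.6, LA = 1)

#' Specification of a synthetic sEMG data set
#'
#' Defines the generative conditions: geometry (subjects, trials, rate,
#' duration), per-class band-weight profiles over the eight level-3 bands,
#' per-class channel gains, the class-separation dial `delta`, the activation
#' envelope and the sensor noise floor. With the defaults the generator
#' emulates the basic-hand-movements recording conditions: 2 channels, 500 Hz,
#' 6 s (3000-sample) trials, 6 movement classes, 30 repetitions per class, and
#' a raw-signal magnitude of about 1e-2 units.
#'
#' @param n_subjects Number of subjects (default 1).
#' @param n_trials_per_class Repetitions of each movement per subject
#'   (default 30).
#' @param rate Sampling rate in Hz (default 500).
#' @param duration Trial length in seconds (default 6).
#' @param delta Class-separation scale: 0 means all classes share identical
#'   generative parameters; 1 is the default moderately separable setting.
#' @param amplitude Plateau amplitude of the activation envelope in signal
#'   units (default 0.01, the raw-data magnitude the noise-level sweep is
#'   anchored to).
#' @param noise_floor Standard deviation of the additive white sensor noise
#'   (default 5e-4, i.e. 5% of `amplitude`).
#' @param ramp Envelope rise/fall time in seconds (default 0.5).
#' @param plateau_jitter Per-trial uniform jitter of the plateau amplitude as a
#'   fraction (default 0.1 for +/-10%), mimicking self-paced effort variation.
#' @param band_weights Optional 6 x 8 matrix of per-class band weights
#'   overriding the built-in profiles.
#' @param channel_ratio Optional 6 x 2 matrix of per-class channel gains.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_subjects = 1L, n_trials_per_class = 30L, rate = 500,
                       duration = 6, delta = 1, amplitude = 0.01,
                       noise_floor = 5e-4, ramp = 0.5, plateau_jitter = 0.1,
                       band_weights = NULL, channel_ratio = NULL) {
  classes <- movement_classes()
  if (is.null(band_weights)) {
    band_weights <- t(vapply(classes, function(cl) {
      w <- .base_band_weights
      sup <- .class_band_support[[cl]]
      w[sup] <- w[sup] * (1 + 0.7 * delta)
      w
    }, numeric(8L)))
  }
  band_weights <- as.matrix(band_weights)
  if (!all(dim(band_weights) == c(6L, 8L)))
    stop("band_weights must be a 6 x 8 matrix")
  if (any(band_weights < 0) || any(rowSums(band_weights) <= 0))
    stop("band weights must be nonnegative with at least one positive per class")
  if (is.null(channel_ratio)) {
    channel_ratio <- cbind(1 + 0.15 * delta * .class_channel_dir,
                           1 - 0.15 * delta * .class_channel_dir)
  }
  channel_ratio <- as.matrix(channel_ratio)
  if (!all(dim(channel_ratio) == c(6L, 2L)) || any(channel_ratio <= 0))
    stop("channel_ratio must be a positive 6 x 2 matrix")
  rownames(band_weights) <- rownames(channel_ratio) <- classes
  n <- as.integer(round(rate * duration))
  if (n < 16L) stop("trial too short")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_class = as.integer(n_trials_per_class),
                 rate = rate, duration = duration, n_samples = n,
                 delta = delta, amplitude = amplitude,
                 noise_floor = noise_floor, ramp = ramp,
                 plateau_jitter = plateau_jitter,
                 classes = classes, band_weights = band_weights,
                 channel_ratio = channel_ratio),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic sEMG spec: %d subject(s) x 6 classes x %d trials, ",
                     "%g Hz x %g s (%d samples), delta = %g\n"),
              x$n_subjects, x$n_trials_per_class, x$rate, x$duration,
              x$n_samples, x$delta))
  invisible(x)
}

# squared spectral mask over the n two-sided DFT bins for one class,
# normalized to unit mean so the shaped noise has unit variance
.class_mask2 <- function(spec, class) {
  n <- spec$n_samples
  w <- spec$band_weights[class, ]
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * spec$rate / n            # two-sided |frequency|
  band <- pmin(floor(f / (spec$rate / 16)) + 1L, 8L)
  m2 <- (w^2)[band]
  m2 / mean(m2)
}

# trapezoidal activation envelope over the trial
.envelope <- function(spec) {
  n <- spec$n_samples
  t <- (seq_len(n) - 1L) / spec$rate
  up <- pmin(t / spec$ramp, 1)
  down <- pmin((spec$duration - t) / spec$ramp, 1)
  pmax(pmin(up, down), 0)
}

#' Generate synthetic sEMG recordings
#'
#' For every trial, white Gaussian noise is shaped in the frequency domain by
#' the trial's class band-weight profile (DFT masking, so band control is
#' exact), scaled per channel by the class channel gain, multiplied by a
#' trapezoidal activation envelope with per-trial plateau jitter, and overlaid
#' with white sensor noise. Fully reproducible from `seed`.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @return List of two-channel `"emg_recording"` objects
#'   (`n_subjects * 6 * n_trials_per_class` of them).
#' @export
generate_recordings <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_samples
  env <- .envelope(spec)
  masks <- lapply(spec$classes, function(cl) sqrt(.class_mask2(spec, cl)))
  names(masks) <- spec$classes
  recs <- vector("list", spec$n_subjects * 6L * spec$n_trials_per_class)
  i <- 0L
  .with_seed(seed, function() {
    for (subj in seq_len(spec$n_subjects)) {
      for (cl in spec$classes) {
        gains <- spec$channel_ratio[cl, ]
        for (tr in seq_len(spec$n_trials_per_class)) {
          a <- spec$amplitude * stats::runif(1, 1 - spec$plateau_jitter,
                                             1 + spec$plateau_jitter)
          samples <- vapply(1:2, function(ch) {
            z <- stats::rnorm(n)
            shaped <- Re(stats::fft(stats::fft(z) * masks[[cl]],
                                    inverse = TRUE)) / n
            a * gains[ch] * env * shaped + spec$noise_floor * stats::rnorm(n)
          }, numeric(n))
          i <<- i + 1L
          recs[[i]] <<- recording(samples, rate = spec$rate, label = cl,
                                  subject = subj, trial = tr)
        }
      }
    }
  })
  recs
}

#' Expected energy per level-3 band of a synthetic class
#'
#' Closed-form expectation of the signal energy falling in each of the eight
#' level-3 frequency bands for one generated trial of `class`, channel
#' `channel`: the band share implied by the class's squared spectral mask,
#' scaled by the expected squared plateau amplitude, the channel gain and the
#' envelope's energy, plus the white noise floor's uniform band share. Serves
#' as the analytic oracle for the measured sub-band energies of decomposed
#' trials.
#'
#' @param spec A [synth_spec()].
#' @param class Class label (one of [movement_classes()]).
#' @param channel Channel index, 1 or 2.
#' @return Numeric vector of length 8 (expected energy per band, signal
#'   units squared).
#' @export
expected_band_energy <- function(spec, class, channel = 1L) {
  stopifnot(inherits(spec, "synth_spec"), class %in% spec$classes)
  n <- spec$n_samples
  m2 <- .class_mask2(spec, class)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * spec$rate / n
  band <- pmin(floor(f / (spec$rate / 16)) + 1L, 8L)
  share <- vapply(1:8, function(b) sum(m2[band == b]), numeric(1L)) / sum(m2)
  bins <- vapply(1:8, function(b) sum(band == b), numeric(1L)) / n
  j <- spec$plateau_jitter
  mean_sq_amp <- spec$amplitude^2 * (1 + j^2 / 3)  # E[U^2], U ~ Unif(1-j, 1+j)
  env_energy <- sum(.envelope(spec)^2)
  gain <- spec$channel_ratio[class, channel]
  mean_sq_amp * gain^2 * env_energy * share + spec$noise_floor^2 * n * bins
}
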