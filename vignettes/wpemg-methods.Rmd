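---
title: "Wavelet packet features for sEMG hand-movement recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet packet features for sEMG hand-movement recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpemg)
```

## The problem and the pipeline

Surface electromyography (sEMG) records the electrical activity of forearm
muscles with skin electrodes. Different hand movements recruit the muscles
under the electrodes differently, which changes both the amplitude and the
spectral content of the recorded signal — so a short window of sEMG carries
enough information to identify the movement being performed. This package
implements a complete recognition pipeline for six grasp types (cylindrical
CY, tip TI, hook HO, palmar PA, spherical SP, lateral LA) recorded with two
bipolar channels at 500 Hz:

1. **Segmentation.** Each trial is cut into fixed-length analysis windows
   (default 400 samples = 0.8 s, non-overlapping).
2. **Wavelet packet transform (WPT).** Each channel of a window is decomposed
   with a full three-level wavelet packet tree into $2^3 = 8$ terminal
   sub-bands that partition $[0, 250]$ Hz into 31.25 Hz strips. Unlike the
   plain discrete wavelet transform, the WPT splits the high-frequency branch
   at every level too, giving uniform frequency resolution.
3. **Features.** From every sub-band's coefficient sequence, four classical
   sEMG descriptors: mean absolute value
   $\mathrm{MAV} = \frac{1}{N}\sum_i |x_i|$, root mean square
   $\mathrm{RMS} = \sqrt{\frac{1}{N}\sum_i x_i^2}$, mean frequency
   $\mathrm{MNF} = \sum_j f_j P_j / \sum_j P_j$, and median frequency
   $\mathrm{MDF}$, the first frequency bin at which the cumulative spectrum
   reaches half the total power. With 2 channels × 8 bands × 4 features the
   window is described by 64 numbers.
4. **PCA.** The 64-dimensional feature space is reduced by principal component
   analysis — eigendecomposition of the $\frac{1}{n} X^\top X$ covariance of
   the centred (and by default standardized, see below) training features —
   keeping the top $k = 30$ components.
5. **Classification.** K-nearest neighbours (Euclidean distance, majority
   vote), a Gaussian-kernel SVM, or bagged decision trees.

The package exposes each stage as a function and the whole chain as one
fitted-model interface:

```{r, eval = FALSE}
recs <- generate_recordings(synth_spec(delta = 2), seed = 1)
fit <- semg_fit(recs)            # dmey, level 3, window 400, PCA-30, KNN
predict(fit, recs[[1]], type = "trial")
cross_validate(recs)             # grouped, stratified 5-fold evaluation
```

## Wavelet packet details

**Bases.** Five orthonormal filter pairs are embedded: `sym3`, `fk8`
(Fejér–Korovkin 8-tap), `dmey` (discrete Meyer, 62 taps), `db4` and `coif2`.
The high-pass filter is always derived from the low-pass table by the
quadrature-mirror relation $g_k = (-1)^k h_{L-1-k}$. `dmey` is the default
basis: its near-brick-wall response localises the 31.25 Hz bands far better
than the short filters (its on-bin energy concentration exceeds 0.9 in every
band, against as little as 0.69 for `db4` in the middle bands — a known
weakness of short-filter wavelet packets).

**Boundary handling.** The default mode is periodization: the window is
zero-padded at the tail to the next multiple of $2^L$ and every
filter-and-decimate step uses circular convolution with alignment
$a_k = \sum_m h_m\, x_{(2k + \lfloor L/2\rfloor - m) \bmod n}$. This makes the
transform exactly orthogonal, so energy is conserved (Parseval) and
`wp_reconstruct()` inverts `wp_decompose()` to machine precision for the
orthonormal bases. A half-point symmetric extension mode is available for
decomposition when wrap-around artifacts matter more than exact invertibility.
Terminal bands are returned in frequency (sequency) order — the Gray-code
permutation of the natural tree order — so band index increases monotonically
with centre frequency.

**The dmey caveat.** The 62-tap discrete Meyer filter is a truncation of an
infinitely supported ideal filter and is only approximately orthonormal. The
embedded table is rescaled to unit energy, which keeps the level-3 energy
defect below $10^{-3}$; the round-trip reconstruction error is bounded by the
residual shift-orthogonality defect at about $4 \times 10^{-3}$ relative, and
the DC gain of a level-3 low-pass cascade is off by about $10^{-2}$. These are
properties of the standard filter itself, not of this implementation, and the
test suite asserts them at exactly these magnitudes (machine-precision bounds
apply to the four exactly orthonormal bases).

**Spectral features on coefficients.** MNF and MDF are computed from an
unwindowed one-sided periodogram of the sub-band *coefficient sequence*, whose
effective sampling rate is $\mathrm{rate}/2^L$ (the sequence is decimated
$2^L$-fold). The alternative — reconstructing each band back to the original
rate first — is available via `spectrum_on = "reconstruction"`. The
periodogram is deliberately the simplest deterministic estimator: no
windowing, no detrending, exact for on-bin sinusoids, so every spectral
feature is verifiable in closed form. A zero-power sub-band (possible for
narrowband signals) yields MNF = MDF = 0 with a warning rather than an error.

## Dimension reduction and scaling

PCA uses the $1/n$ covariance normalisation of the centred data and fixes
eigenvector signs so the largest-magnitude loading is positive, making
serialized models reproducible. Eigenvalue ties are left in
eigendecomposition order.

The pipeline standardizes features before PCA by default
(`standardize = TRUE`). This is a deliberate design choice: MAV/RMS are in
signal units (around $10^{-2}$ for typical recordings) while MNF/MDF are in
Hz (tens), so the unstandardized covariance is dominated by the spectral
block by roughly six orders of magnitude and the top-30 eigenvectors span
almost no amplitude information. On the synthetic reference conditions this
costs about 30 accuracy points at high class separation. The `pca_fit()`
primitive itself defaults to centring only, matching the usual
"decentralised covariance" formulation; pass `standardize = FALSE` to the
pipeline functions to reproduce that behaviour end-to-end.

## Classifiers

* **KNN** (default, $K = 5$): Euclidean distance, majority vote; vote ties
  are broken by the smallest summed distance among the tied classes, then by
  class order, so predictions are fully deterministic. $K$ is odd to reduce
  ties; the value is a common default, not tuned.
* **SVM**: radial-basis kernel via libsvm (one-vs-one multiclass voting);
  defaults $C = 1$, $\gamma = 1/(p \cdot \overline{\mathrm{var}})$.
* **Bagging**: 100 fully grown decision trees on bootstrap resamples,
  plurality vote; the resampling is drawn from the supplied seed, so training
  is bit-reproducible.

KNN and SVM z-score the feature columns internally with training-fold
statistics (distance-based methods need commensurate scales); trees are
scale-invariant and left unscaled.

## Evaluation protocol

`cross_validate()` runs stratified $k$-fold cross-validation **grouped by
trial**: all windows cut from one trial are assigned to the same fold. Windows
of a trial overlap in time and share the trial's activation level, so
splitting them across folds would leak test information into training and
inflate accuracy. Within each fold the standardizer, the PCA projection and
the classifier are fitted on training windows only (the test suite re-derives
one full fold loop from the exported primitives and checks the summed
confusion matrix agrees exactly). With several subjects, each subject is
evaluated separately and fold accuracies are averaged (`subject_mode =
"pooled"` pools everyone). Reported accuracy is the mean over folds (and
subjects) of the fold's window-level accuracy; the standard deviation over
folds is also reported.

Per-class metrics follow the one-vs-rest convention: for each class,
TP/TN/FP/FN give accuracy, recall, precision and F1 (F1 is set to 0 with a
warning when precision + recall = 0).

The four experiment runners sweep one factor at a fixed configuration:
wavelet basis (`sweep_basis`), retained PCA dimension (`sweep_dimension`,
10–50), test-time noise (`sweep_noise`), and window size (`sweep_window`,
200–400 samples). The noise sweep trains on clean windows and evaluates on
windows perturbed with zero-mean Gaussian noise of standard deviation
$\mathrm{level} \times \mathrm{reference}$, re-extracting features from the
perturbed signals; `reference_magnitude` defaults to 1 (absolute units) and
should be set to the data magnitude (e.g. 0.01) when levels are meant
relative to it. `kruskal_wallis_screen()` applies the tie-corrected
Kruskal–Wallis rank test (χ², $k-1$ df) to each retained component.

## The synthetic generator

`synth_spec()` / `generate_recordings()` produce labelled trials without any
external data, emulating the reference recording conditions: 2 channels,
500 Hz, 6 s trials, 6 classes, 30 repetitions per class, raw magnitude about
$10^{-2}$ signal units. Per trial, white Gaussian noise is shaped in the
frequency domain by the class's weight profile over the eight level-3 bands
(DFT masking — exact band control with no filter transition bands to reason
about), scaled per channel by a class-specific gain, multiplied by a
trapezoidal activation envelope (0.5 s ramps, ±10% per-trial plateau jitter
mimicking self-paced effort), and overlaid with a white sensor-noise floor
(5% of the plateau amplitude).

Classes differ in two ways, both scaled by the separation dial $\delta$: each
class boosts two class-specific bands of a common decaying base spectrum by
$1 + 0.7\delta$ (adjacent classes share one boosted band, so the problem is
separable but not trivial), and the two channel gains split as
$1 \pm 0.15\,\delta\,u_c$ with class-specific directions $u_c$. At
$\delta = 0$ all classes are generatively identical — cross-validated
accuracy must sit at the 1/6 chance level, which the tests assert within
three binomial standard errors using the *trial* as the independent unit
(windows within a trial are correlated). `expected_band_energy()` gives the
closed-form expected energy per band implied by the mask, envelope, gains and
noise floor, and serves as the analytic oracle for Monte-Carlo checks.

What the generator deliberately does **not** model: motor-unit action
potentials and their firing statistics, electrode lift/shift artifacts,
inter-subject anatomy, within-trial spectral drift from fatigue. Classes
differ only through stationary band power and channel ratio, so a pipeline
that passes here is validated for its *mechanics* (energy bookkeeping,
leakage-free evaluation, monotone responses to noise and window size), not
for clinical performance on real muscles.

## Numerical choices and degenerate inputs

* Windows shorter than the configured length are discarded; stride is
  `round(window_length * (1 - overlap))` and must be at least 1.
* Non-finite samples are a hard validation error everywhere (no imputation).
* Lengths not divisible by $2^L$ are zero-padded at the tail (periodization);
  the original length is stored and restored on reconstruction.
* MDF uses the smallest-index rule at the half-power point, without
  interpolation — the defining sum is discrete and interpolation would invent
  precision.
* Zero-variance columns are an error under standardized PCA, and are given
  unit scale inside the classifiers' z-scoring.
* Constant feature columns in the Kruskal–Wallis screen give $H = 0$,
  $p = 1$ with a warning.
* All randomness (fold shuffling, bagging bootstrap, noise injection,
  generation) flows from explicit integer seeds; identical seeds give
  bit-identical results.

## Problem sizes used in the checks

The packaged tests and the acceptance script run entirely on the synthetic
generator. The acceptance script uses the full reference geometry (1 subject,
6 × 30 trials of 3000 samples; 1260 windows of 400 samples; 64 features;
PCA-30; 5-fold grouped CV) for the end-to-end numbers, and 200-sample to
400-sample random signals for the transform checks. Unit tests use reduced
sets (typically 6 trials per class) where the property under test does not
need the full geometry.

## Known limitations

* `dmey` is not exactly orthonormal (see above); if exact invertibility
  matters, use `db4`, `sym3`, `coif2` or `fk8`.
* The symmetric-extension mode has no inverse transform here.
* The MAT v5 reader covers real numeric matrices (plain or zlib-compressed) —
  the layout of the public basic-hand-movements archive — not cells, structs,
  or v7.3/HDF5 containers.
* SVM and bagging hyperparameters are sensible defaults, not tuned; KNN's
  $K$, SVM's $(C, \gamma)$ and the tree count are all exposed.
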