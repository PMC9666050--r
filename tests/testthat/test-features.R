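test_that("MAV and RMS reproduce hand-computed values", {
  expect_equal(mav(c(1, -1, 1, -1)), 1)
  expect_equal(mav(c(0, 0, 0)), 0)
  expect_equal(mav(c(3, -4)), 3.5)
  expect_equal(rms(c(1, -1, 1, -1)), 1)
  expect_equal(rms(c(3, -4)), sqrt(12.5))
  expect_equal(rms(0), 0)
  expect_error(mav(numeric(0)), "empty")
  expect_error(rms(numeric(0)), "empty")
})

test_that("MAV <= RMS and both are absolutely scale-equivariant", {
  set.seed(7)
  for (i in 1:1000) {
    x <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 10))
    expect_lte(mav(x), rms(x) + 1e-15)
  }
  x <- rnorm(100)
  for (a in c(-3.7, 0.01, 250)) {
    expect_equal(mav(a * x), abs(a) * mav(x))
    expect_equal(rms(a * x), abs(a) * rms(x))
    s1 <- power_spectrum(x, 500)
    s2 <- power_spectrum(a * x, 500)
    expect_equal(mnf(s2), mnf(s1))
    expect_equal(mdf(s2), mdf(s1))
  }
})

test_that("the periodogram is exact for on-bin sinusoids and conserves energy", {
  n <- 256
  rate <- 500
  f0 <- 20 * rate / n  # exactly on bin 20
  x <- cos(2 * pi * f0 * (0:(n - 1)) / rate)
  s <- power_spectrum(x, rate)
  expect_equal(which.max(s$power), 21L)  # bin index 20, 1-based 21
  expect_lt(sum(s$power[-21]) / s$power[21], 1e-20)
  # Parseval: sum over the full two-sided spectrum equals N * sum(x^2)
  y <- rnorm(101)
  full <- Mod(stats::fft(y))^2
  expect_equal(sum(full), length(y) * sum(y^2))
  expect_error(power_spectrum(1, 500), "at least 2")
  expect_equal(power_spectrum(rep(0, 16), 500)$power, rep(0, 9))
})

test_that("MNF and MDF reproduce hand-computed values and conventions", {
  sp <- function(f, p) structure(list(freqs = f, power = p),
                                 class = "emg_spectrum")
  expect_equal(mnf(sp(c(10, 20), c(1, 1))), 15)
  expect_equal(mnf(sp(c(10, 20), c(0, 5))), 20)
  expect_warning(expect_equal(mnf(sp(c(10, 20), c(0, 0))), 0), "zero")
  expect_equal(mdf(sp(c(0, 10, 20), c(1, 2, 1))), 10)
  expect_equal(mdf(sp(c(0, 10, 20), c(4, 0, 0))), 0)
  expect_equal(mdf(sp(c(10, 20), c(1, 1))), 10)  # smallest-index tie rule
  expect_warning(expect_equal(mdf(sp(c(10, 20), c(0, 0))), 0), "zero")
})

test_that("MNF and MDF locate an on-bin sinusoid within one bin", {
  n <- 400
  rate <- 500
  bin <- rate / n
  for (f0 in c(10, 62.5, 180)) {
    f0 <- round(f0 / bin) * bin
    x <- sin(2 * pi * f0 * (0:(n - 1)) / rate)
    s <- power_spectrum(x, rate)
    expect_lt(abs(mnf(s) - f0), bin + 1e-9)
    expect_lt(abs(mdf(s) - f0), bin + 1e-9)
  }
})

test_that("per-window extraction yields the canonical 64-column layout", {
  w <- list(samples = matrix(rnorm(800), ncol = 2), rate = 500)
  v <- extract_features(w, basis = "db4", level = 3)
  expect_length(v, 64L)
  expect_identical(names(v), feature_names(2, 3))
  expect_identical(names(v)[1:4], c("ch1_band1_MAV", "ch1_band1_RMS",
                                    "ch1_band1_MNF", "ch1_band1_MDF"))
  expect_identical(names(v)[64], "ch2_band8_MDF")
  # one channel, one level: 1 x 2 x 4 = 8 values
  w1 <- list(samples = matrix(rnorm(400), ncol = 1), rate = 500)
  expect_length(extract_features(w1, basis = "db4", level = 1), 8L)
})

test_that("an all-zero window yields zero features with a warning", {
  w <- list(samples = matrix(0, 400, 2), rate = 500)
  msgs <- capture_warnings(v <- extract_features(w, basis = "db4", level = 3))
  expect_length(msgs, 16L)  # one per channel x band
  expect_true(all(grepl("zero-power", msgs)))
  expect_true(all(v == 0))
})

test_that("sub-band RMS recovers window energy (Parseval link)", {
  set.seed(8)
  w <- list(samples = matrix(rnorm(800), ncol = 2), rate = 500)
  v <- extract_features(w, basis = "db4", level = 3)
  for (ch in 1:2) {
    rms_cols <- v[paste0("ch", ch, "_band", 1:8, "_RMS")]
    # each band holds 400/8 = 50 coefficients
    expect_equal(sum(rms_cols^2 * 50), sum(w$samples[, ch]^2), tolerance = 1e-8)
  }
})

test_that("reconstructed-signal spectral mode measures at the original rate", {
  n <- 400
  rate <- 500
  # narrowband signal in band 6 (156.25-187.5 Hz)
  f0 <- 170
  w <- list(samples = matrix(sin(2 * pi * f0 * (0:(n - 1)) / rate), ncol = 1),
            rate = rate)
  v <- extract_features(w, basis = "db4", level = 3,
                        spectrum_on = "reconstruction")
  m <- v["ch1_band6_MNF"]
  rng <- subband_frequency_range(3, 6, rate)
  expect_gte(m, rng[1] - 10)
  expect_lte(m, rng[2] + 10)
  # coefficient mode reports on the decimated axis [0, rate/16]
  vc <- extract_features(w, basis = "db4", level = 3)
  expect_lte(vc["ch1_band6_MNF"], rate / 16)
})

test_that("feature matrices stack windows with metadata and round-trip CSV", {
  recs <- cached_recordings(delta = 2, trials = 6)
  windows <- segment_recordings(recs[1:6], 400)
  fm <- feature_matrix(windows, basis = "db4", level = 3)
  expect_equal(dim(fm$values), c(6 * 7, 64))
  expect_identical(colnames(fm$values), feature_names(2, 3))
  expect_equal(unique(fm$labels), "CY")
  path <- tempfile(fileext = ".csv")
  write_features_csv(fm, path)
  back <- read_features_csv(path, basis = "db4", level = 3)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_identical(back$labels, fm$labels)
  expect_identical(back$trials, fm$trials)
})
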