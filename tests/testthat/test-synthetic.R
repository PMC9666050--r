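test_that("the default spec reproduces the study geometry", {
  spec <- synth_spec()
  expect_equal(spec$n_trials_per_class, 30L)
  expect_equal(spec$rate, 500)
  expect_equal(spec$n_samples, 3000L)
  recs <- generate_recordings(synth_spec(n_trials_per_class = 2), seed = 1)
  expect_length(recs, 12L)  # 1 subject x 6 classes x 2 trials
  expect_true(all(vapply(recs, function(r) nrow(r$samples) == 3000L, TRUE)))
  expect_true(all(vapply(recs, function(r) ncol(r$samples) == 2L, TRUE)))
  expect_equal(sort(unique(vapply(recs, function(r) r$label, ""))),
               sort(movement_classes()))
})

test_that("generation is deterministic in the seed and signals are sane", {
  spec <- synth_spec(n_trials_per_class = 2)
  r1 <- generate_recordings(spec, seed = 5)
  r2 <- generate_recordings(spec, seed = 5)
  expect_identical(lapply(r1, `[[`, "samples"), lapply(r2, `[[`, "samples"))
  r3 <- generate_recordings(spec, seed = 6)
  expect_gt(max(abs(r1[[1]]$samples - r3[[1]]$samples)), 0)
  x <- do.call(rbind, lapply(r1, `[[`, "samples"))
  expect_true(all(is.finite(x)))
  # zero mean within 3 standard errors
  expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)))
  # magnitude matches the configured 1e-2 amplitude scale
  expect_lt(sd(x), 0.05)
  expect_gt(sd(x), 1e-3)
})

test_that("delta = 0 collapses all classes onto identical parameters", {
  spec <- synth_spec(delta = 0)
  expect_true(all(apply(spec$band_weights, 2, function(col)
    max(col) - min(col) == 0)))
  expect_true(all(spec$channel_ratio == 1))
})

test_that("expected band energies follow the analytic construction", {
  # single-band class profile: all expected signal energy in that band
  w <- matrix(0, 6, 8)
  w[, 3] <- 1
  spec <- synth_spec(band_weights = w, channel_ratio = matrix(1, 6, 2),
                     noise_floor = 0)
  e <- expected_band_energy(spec, "CY")
  expect_true(all(e[-3] == 0))
  expect_gt(e[3], 0)
  # doubling the amplitude of one band quadruples its share against a flat rest
  w2 <- matrix(1, 6, 8)
  w2[1, 5] <- 2
  spec2 <- synth_spec(band_weights = w2, channel_ratio = matrix(1, 6, 2),
                      noise_floor = 0)
  e2 <- expected_band_energy(spec2, "CY")
  expect_equal(e2[5] / e2[1], 4, tolerance = 0.02)
})

measured_band_energy <- function(recs, cl, basis = "dmey") {
  sel <- Filter(function(r) r$label == cl, recs)
  Reduce(`+`, lapply(sel, function(r) {
    s <- wp_decompose(r$samples[, 1], basis, 3)
    vapply(s$coeffs, function(cc) sum(cc^2), numeric(1))
  })) / length(sel)
}

test_that("measured sub-band energies match the analytic oracle within 10%", {
  # delta = 0: adjacent band weights are within 25% of each other, so filter
  # transition-band leakage between neighbours stays well below the tolerance
  spec <- synth_spec(n_trials_per_class = 20, delta = 0)
  recs <- generate_recordings(spec, seed = 9)
  measured <- measured_band_energy(recs, "CY")
  oracle <- expected_band_energy(spec, "CY", channel = 1)
  expect_lt(max(abs(measured - oracle) / oracle), 0.10)
})

test_that("boosted-band energy ratios follow the oracle when classes separate", {
  spec <- synth_spec(n_trials_per_class = 8, delta = 1)
  recs <- generate_recordings(spec, seed = 9)
  # CY boosts bands 1-2: compare a boosted band against a distant flat band
  measured <- measured_band_energy(recs, "CY")
  oracle <- expected_band_energy(spec, "CY", channel = 1)
  expect_equal(measured[1] / measured[5], oracle[1] / oracle[5],
               tolerance = 0.2)
  # the cross-delta change of the boosted band (spectral share up, CY channel-1
  # gain down) also follows the closed form
  spec0 <- synth_spec(n_trials_per_class = 8, delta = 0)
  measured0 <- measured_band_energy(generate_recordings(spec0, seed = 9), "CY")
  oracle0 <- expected_band_energy(spec0, "CY", channel = 1)
  expect_equal(measured[1] / measured0[1], oracle[1] / oracle0[1],
               tolerance = 0.15)
})

test_that("a narrowband class puts its full-signal MNF inside the dominant band", {
  w <- matrix(0, 6, 8)
  w[, 4] <- 1  # all classes narrowband in band 4 (93.75-125 Hz)
  spec <- synth_spec(band_weights = w, noise_floor = 1e-5,
                     n_trials_per_class = 3)
  recs <- generate_recordings(spec, seed = 10)
  rng <- subband_frequency_range(3, 4, spec$rate)
  m <- mean(vapply(recs, function(r)
    mnf(power_spectrum(r$samples[, 1], r$rate)), numeric(1)))
  expect_gte(m, rng[1])
  expect_lte(m, rng[2])
})

test_that("invalid specs are rejected", {
  expect_error(synth_spec(band_weights = matrix(1, 5, 8)), "6 x 8")
  expect_error(synth_spec(band_weights = matrix(-1, 6, 8)), "nonnegative")
  expect_error(synth_spec(channel_ratio = matrix(0, 6, 2)), "positive")
})
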