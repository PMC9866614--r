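test_that("a unit cosine at an exact bin frequency has closed-form spectrum", {
  seg <- cosine_segment(1.0, 48L, 4)
  sp <- amplitude_spectrum(seg)
  expect_identical(length(sp$magnitudes), 25L)
  expect_equal(sp$resolution, 1 / 12)
  expect_equal(sp$magnitudes[13], 24, tolerance = 1e-9)  # bin 12 = 1.0 Hz
  expect_lt(max(sp$magnitudes[-13]), 1e-9)
  expect_equal(sp$frequencies[13], 1.0)
  expect_equal(sp$frequencies[25], 2.0)  # Nyquist bin = fs/2
})

test_that("amplitude_spectrum matches the direct O(N^2) summation", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(48)
    expect_lt(max(abs(amplitude_spectrum(x, fs = 4)$magnitudes -
                        brute_dft_onesided(x))), 1e-9)
  }
  # odd lengths keep floor(N/2) + 1 bins
  set.seed(77)
  x <- rnorm(47)
  expect_lt(max(abs(amplitude_spectrum(x, fs = 4)$magnitudes -
                      brute_dft_onesided(x))), 1e-9)
  expect_error(amplitude_spectrum(1, fs = 4), "at least 2")
})

test_that("one-sided Parseval identity holds on random segments", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(48)
    m <- amplitude_spectrum(x, fs = 4)$magnitudes
    lhs <- sum(x^2)
    rhs <- (m[1]^2 + 2 * sum(m[2:24]^2) + m[25]^2) / 48
    expect_equal(rhs, lhs, tolerance = 1e-6)
  }
})

test_that("mean-removed constant segment transforms to all zeros", {
  seg <- preprocess_segment(make_segment(rep(4.2, 48)), "mean-removal")
  expect_lt(max(amplitude_spectrum(seg)$magnitudes), 1e-12)
})

test_that("energy normalization rescales to unit spectral energy", {
  sp <- amplitude_spectrum(cosine_segment(1.0, 48L, 4))
  out <- normalize_spectrum(sp, "energy")
  expect_equal(out$magnitudes[13], 1.0, tolerance = 1e-12)
  expect_identical(normalize_spectrum(sp, "none"), sp)
  for (seed in 1:5) {
    set.seed(seed)
    sp2 <- amplitude_spectrum(rnorm(48), fs = 4)
    expect_equal(sum(normalize_spectrum(sp2, "energy")$magnitudes^2), 1,
                 tolerance = 1e-12)
  }
  zero <- amplitude_spectrum(rep(0, 48), fs = 4)
  expect_warning(out0 <- normalize_spectrum(zero, "energy"), "all-zero")
  expect_identical(out0$magnitudes, zero$magnitudes)
})

test_that("band bins follow the edge rule and partition the axis", {
  sp <- amplitude_spectrum(rnorm(48), fs = 4)
  # half-open [1, 2): bins 12..23, N_b = 12 at resolution 1/12 Hz
  b12 <- band_bins(sp, frequency_band(1, 2))
  expect_identical(b12, 13:24)
  expect_length(b12, 12L)
  # closed [1, 2] keeps the Nyquist bin too
  expect_identical(band_bins(sp, frequency_band(1, 2, "closed")), 13:25)
  # [0, fs/2) half-open: everything but the Nyquist bin
  expect_identical(band_bins(sp, frequency_band(0, 2)), 1:24)
  # adjacent half-open bands are disjoint and jointly exhaustive below 2 Hz
  b01 <- band_bins(sp, frequency_band(0, 1))
  expect_length(intersect(b01, b12), 0L)
  expect_identical(sort(c(b01, b12)), 1:24)
  # a band thinner than the resolution holds no bin
  expect_error(band_bins(sp, frequency_band(0.01, 0.02)),
               class = "edafreq_empty_band")
  expect_error(band_bins(sp, frequency_band(1, 3)), "Nyquist")
})

test_that("band mean/std/max equal hand-computed values on the cosine", {
  sp <- amplitude_spectrum(cosine_segment(1.0, 48L, 4))
  band <- frequency_band(1, 2)
  expect_equal(band_mean(sp, band), 2.0, tolerance = 1e-9)   # 24 / 12
  expect_equal(band_std(sp, band), sqrt(48), tolerance = 1e-9)  # sqrt(528/11)
  expect_equal(band_max(sp, band), 24, tolerance = 1e-9)
  # the cosine has nothing below 1 Hz
  low <- frequency_band(0, 1)
  expect_equal(band_mean(sp, low), 0, tolerance = 1e-9)
  expect_equal(band_max(sp, low), 0, tolerance = 1e-9)
})

test_that("band std matches the two-pass textbook formula", {
  for (seed in 1:5) {
    set.seed(seed)
    sp <- amplitude_spectrum(rnorm(48), fs = 4)
    band <- frequency_band(0, 1)
    m <- sp$magnitudes[band_bins(sp, band)]
    expect_equal(band_std(sp, band),
                 sqrt(sum((m - mean(m))^2) / (length(m) - 1)),
                 tolerance = 1e-12)
  }
  sp1 <- amplitude_spectrum(rnorm(4), fs = 4)
  expect_error(band_std(sp1, frequency_band(0, 0.5)),
               class = "edafreq_empty_band")
})

test_that("energy profile is a normalized running sum", {
  sp <- amplitude_spectrum(cosine_segment(1.0, 48L, 4))
  prof <- energy_profile(sp)
  expect_false(prof$include_dc)
  # all energy in one bin: psi_cum jumps from ~0 to 1 at 1.0 Hz
  expect_lt(prof$psi_cum[11], 1e-12)
  expect_equal(prof$psi_cum[12], 1, tolerance = 1e-9)
  for (seed in 1:5) {
    set.seed(seed)
    sp2 <- amplitude_spectrum(rnorm(48), fs = 4)
    prof2 <- energy_profile(sp2)
    expect_equal(prof2$psi_cum,
                 cumsum(sp2$magnitudes[-1]^2) / sum(sp2$magnitudes[-1]^2),
                 tolerance = 1e-12)
    expect_true(all(diff(prof2$psi_cum) >= -1e-15))
    expect_equal(prof2$psi_cum[length(prof2$psi_cum)], 1,
                 tolerance = 1e-9)
  }
  expect_error(energy_profile(amplitude_spectrum(rep(0, 48), fs = 4)),
               class = "edafreq_zero_energy")
})

test_that("half-energy frequency solves the discrete cumulative rule", {
  # single tone: all energy at its bin
  sp <- amplitude_spectrum(cosine_segment(1.0, 48L, 4))
  expect_equal(half_energy_frequency(energy_profile(sp)), 1.0)
  # equal-energy tones at 0.5 and 1.5 Hz: cumulative hits exactly 0.5
  # at the lower bin
  x <- cos(2 * pi * 0.5 * (0:47) / 4) + cos(2 * pi * 1.5 * (0:47) / 4)
  sp2 <- amplitude_spectrum(x, fs = 4)
  expect_equal(half_energy_frequency(energy_profile(sp2)), 0.5)
  # flat spectrum over bins 1..24: midpoint bin 12 -> 1.0 Hz
  sp3 <- amplitude_spectrum(rnorm(48), fs = 4)
  sp3$magnitudes <- c(0, rep(1, 24))
  expect_equal(half_energy_frequency(energy_profile(sp3)), 1.0)
})

test_that("half-energy frequency is invariant under positive rescaling", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(48)
    f1_ <- half_energy_frequency(energy_profile(amplitude_spectrum(x, 4)))
    for (scale in c(1e-3, 7, 1e4)) {
      f2_ <- half_energy_frequency(
        energy_profile(amplitude_spectrum(scale * x, 4)))
      expect_identical(f2_, f1_)
    }
  }
})

test_that("segment features follow the 3m+1 layout", {
  set.seed(8)
  seg <- preprocess_segment(make_segment(runif(48, 2, 8)), "mean-removal")
  feats <- extract_segment_features(seg)
  expect_length(feats, 7L)  # m = 2 bands
  expect_identical(names(feats),
                   c("mean_0.0_1.0", "sd_0.0_1.0", "max_0.0_1.0",
                     "mean_1.0_2.0", "sd_1.0_2.0", "max_1.0_2.0",
                     "fhalf"))
  one_band <- list(frequency_band(0, 2))
  expect_length(extract_segment_features(seg, one_band), 4L)  # m = 1
  # zero-energy (constant, mean-removed) segments propagate the typed error
  flat <- preprocess_segment(make_segment(rep(5, 48)), "mean-removal")
  expect_error(extract_segment_features(flat),
               class = "edafreq_zero_energy")
})

test_that("band features on the cosine flow through extract_segment_features", {
  feats <- extract_segment_features(cosine_segment(1.0, 48L, 4))
  expect_equal(unname(feats["mean_1.0_2.0"]), 2.0, tolerance = 1e-9)
  expect_equal(unname(feats["sd_1.0_2.0"]), sqrt(48), tolerance = 1e-9)
  expect_equal(unname(feats["max_1.0_2.0"]), 24, tolerance = 1e-9)
  expect_equal(unname(feats["fhalf"]), 1.0)
})

test_that("band energies over a half-open partition sum to the total", {
  bands <- list(frequency_band(0, 0.5), frequency_band(0.5, 1),
                frequency_band(1, 1.5), frequency_band(1.5, 2))
  for (seed in 1:5) {
    set.seed(seed)
    sp <- amplitude_spectrum(rnorm(48), fs = 4)
    band_energy <- sum(vapply(bands, function(b) {
      sum(sp$magnitudes[band_bins(sp, b)]^2)
    }, numeric(1)))
    non_nyquist <- sum(sp$magnitudes[-25]^2)
    expect_equal(band_energy, non_nyquist, tolerance = 1e-12)
  }
})
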