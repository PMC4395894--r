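test_that("deformation field recovers offsets and the baseline window rule", {
  # constant contours -> zero deformation everywhere
  outer <- matrix(80, 20, 50)
  f <- compute_deformation_field(contours_from_matrix(outer), 5)
  expect_true(all(f$full == 0))
  expect_equal(f$baseline, rep(80, 50))

  # a +5 px shift after the baseline window is recovered exactly
  outer[11:20, ] <- 85
  f <- compute_deformation_field(contours_from_matrix(outer), 5)
  expect_true(all(f$full[11:20, ] == 5))
  expect_true(all(abs(f$full[1:5, ]) < 1e-12))

  expect_error(compute_deformation_field(contours_from_matrix(outer), 0),
               "baseline_frames")
  expect_error(compute_deformation_field(contours_from_matrix(outer), 20),
               "baseline_frames")
})

test_that("eyeball/cornea split separates translation from central bumps", {
  w <- 200
  # pure whole-eye translation: everything goes to the eyeball component
  outer <- matrix(70, 30, w)
  outer[16:30, ] <- 73
  f <- split_eyeball_cornea(compute_deformation_field(contours_from_matrix(outer), 5),
                            scleral_margin = 25)
  expect_lt(max(abs(f$eyeball[16:30, ] - 3)), 1e-12)
  expect_lt(max(abs(f$cornea)), 1e-12)

  # compactly supported central bump: eyeball stays at zero
  x <- 1:w
  bump <- ifelse(abs(x - 100) < 40, cos((x - 100) / 40 * pi / 2)^2, 0)
  oc <- matrix(70, 30, w) +
    outer(c(rep(0, 5), seq(0, 10, length.out = 25)), bump)
  f <- split_eyeball_cornea(compute_deformation_field(contours_from_matrix(oc), 5),
                            scleral_margin = 25)
  expect_lt(max(abs(f$eyeball)), 1e-9)
  expect_equal(f$cornea, f$full)

  expect_error(split_eyeball_cornea(
    compute_deformation_field(contours_from_matrix(oc), 5), 100),
    "scleral_margin")
})

test_that("split recovers translation ramp and bump on rendered sequences", {
  # bump width chosen so the corneal deformation truly vanishes at the
  # scleral margins; otherwise the linear eyeball model absorbs the leak
  cfg <- small_config(noise_sigma = 0, eyeball_left_px = 5, eyeball_right_px = 5,
                      bump_sigma_px = 30)
  r <- render_sequence(cfg)
  an <- analyze_sequence(r$sequence, baseline_frames = 5, scleral_margin = 30)
  g_true <- rowMeans(r$truth$eyeball_true)  # flat translation per frame
  L <- an$field$anchors_left
  expect_lte(max(abs(L - g_true)), 0.2)
  expect_lte(max(abs(an$field$cornea - r$truth$cornea_true)), 0.5)
})

test_that("high-pass isolates fast oscillations and passes purity", {
  n <- 140; dt <- 231e-6
  fs <- 1 / dt
  t <- 0:(n - 1)
  # constant corneal series -> zero vibration
  f <- field_from_matrix(matrix(50, n, 80), baseline_frames = 10, margin = 10)
  expect_lt(max(abs(f$vibration)), 1e-9)

  # bin-centred 309.2 Hz unit sinusoid passes through almost unchanged
  f0 <- 10 * fs / n
  outer <- matrix(60, n, 80)
  outer[, 40] <- 60 + sin(2 * pi * f0 * t * dt)
  f <- field_from_matrix(outer, baseline_frames = 10, margin = 10)
  f$cornea <- outer - 60  # isolate the sinusoid as the corneal component
  f <- highpass_vibration(f, 100)
  expect_lt(abs(max(f$vibration[, 40]) - 1), 0.05)
  expect_lt(max(abs(f$cornea_low[, 40])), 0.05)

  # slow ramp: the high-pass residue equals an explicit DFT-mask oracle
  # (a ramp is a sawtooth to the DFT, so its Gibbs ripple legitimately
  # reaches ~2 px at the window edges; the bound is frozen from the oracle)
  ramp <- seq(0, 5, length.out = n)
  f$cornea <- matrix(ramp, n, 80)
  f <- highpass_vibration(f, 100)
  W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  Xr <- as.vector(W %*% ramp)
  keep <- pmin(0:(n - 1), n - 0:(n - 1)) * fs / n >= 100
  oracle <- Re(Conj(W) %*% (Xr * keep)) / n
  expect_lt(max(abs(f$vibration[, 1] - oracle)), 1e-8)
  expect_lt(max(abs(f$vibration)), 2.5)

  # spectral purity below the cutoff, well under machine noise scale
  f$cornea <- matrix(rnorm(n * 80), n, 80)
  f <- highpass_vibration(f, 100)
  X <- Mod(stats::mvfft(f$vibration))
  freqs <- pmin(0:(n - 1), n - 0:(n - 1)) * fs / n
  expect_lt(max(X[freqs < 100, ]), 1e-9)

  expect_error(highpass_vibration(f, fs), "Nyquist")
})

test_that("decomposition additivity and linearity hold to machine precision", {
  for (s in 1:3) {
    cfg <- small_config(seed = s, vib_frequency_hz = 400, vib_amplitude_px = 0.5)
    r <- render_sequence(cfg)
    f <- analyze_sequence(r$sequence, baseline_frames = 5,
                          scleral_margin = 30)$field
    expect_lt(max(abs(f$full - (f$eyeball + f$cornea))), 1e-9)
    expect_lt(max(abs(f$cornea - (f$cornea_low + f$vibration))), 1e-9)
  }
  # linearity: decompose(a + b) = decompose(a) + decompose(b)
  set.seed(4)
  oa <- matrix(rnorm(60 * 40, 70, 2), 60, 40)
  ob <- matrix(rnorm(60 * 40, 90, 2), 60, 40)
  fa <- field_from_matrix(oa, 5, 8)
  fb <- field_from_matrix(ob, 5, 8)
  fab <- field_from_matrix(oa + ob, 5, 8)
  for (comp in c("full", "eyeball", "cornea", "cornea_low", "vibration")) {
    expect_lt(max(abs(fab[[comp]] - (fa[[comp]] + fb[[comp]]))), 1e-8)
  }
})

test_that("amplitude spectrum is single-sided, exact on lines, Parseval-true", {
  n <- 140; dt <- 231e-6; fs <- 1 / dt
  t <- 0:(n - 1)
  f0 <- 12 * fs / n
  f <- field_from_matrix(matrix(50, n, 20), baseline_frames = 10, margin = 4)
  f$cornea <- matrix(0, n, 20)
  f$cornea[, 7] <- 0.8 * sin(2 * pi * f0 * t * dt)
  sp <- fft_amplitude_map(f)
  expect_equal(sp$freqs, (0:70) * fs / n)
  expect_equal(sp$sampling_rate_hz, fs)
  expect_lt(abs(sp$amplitude[13, 7] - 0.8), 1e-9)
  expect_true(all(sp$amplitude >= 0))
  # all-zero signal -> all-zero map
  expect_true(all(sp$amplitude[, -7] == 0))

  # Parseval: time-domain energy equals the spectral reconstruction
  set.seed(8)
  f$cornea[, 3] <- rnorm(n)
  sp <- fft_amplitude_map(f)
  e_time <- sum(f$cornea[, 3]^2) / n
  a <- sp$amplitude[, 3]
  e_spec <- a[1]^2 + sum((a[2:70] / 2)^2 * 2) + a[71]^2
  expect_lt(abs(e_time - e_spec) / e_time, 1e-9)
})

test_that("first harmonic picks the dominant line and handles silence", {
  n <- 140; dt <- 231e-6; fs <- 1 / dt
  t <- 0:(n - 1)
  f <- field_from_matrix(matrix(50, n, 30), baseline_frames = 10, margin = 5)
  base <- matrix(0, n, 30)
  # two lines: 154.6 Hz at 0.1 px and 401.98 Hz at 0.3 px -> the bigger wins
  f$cornea <- base
  f$cornea[, 15] <- 0.1 * sin(2 * pi * (5 * fs / n) * t * dt) +
                    0.3 * sin(2 * pi * (13 * fs / n) * t * dt)
  fh <- first_harmonic(fft_amplitude_map(f))
  expect_equal(fh$frequency_hz, 13 * fs / n, tolerance = 1e-9)
  expect_equal(fh$amplitude_px, 0.3, tolerance = 1e-6)
  expect_equal(fh$column, 14L)
  expect_equal(fh$resolution_hz, fs / n)

  # single bin-centred line is recovered exactly
  f$cornea <- base
  f$cornea[, 3] <- 0.25 * sin(2 * pi * (10 * fs / n) * t * dt)
  fh <- first_harmonic(fft_amplitude_map(f))
  expect_equal(fh$frequency_hz, 10 * fs / n, tolerance = 1e-9)
  expect_equal(fh$amplitude_px, 0.25, tolerance = 1e-9)

  # silence reports zero amplitude and no frequency
  f$cornea <- base
  fh <- first_harmonic(fft_amplitude_map(f))
  expect_equal(fh$amplitude_px, 0)
  expect_true(is.na(fh$frequency_hz))

  expect_error(first_harmonic(fft_amplitude_map(f), min_freq_hz = fs),
               "min_freq_hz")
})

test_that("median filter is exact against the brute-force oracle", {
  set.seed(13)
  m <- matrix(rnorm(20 * 30), 20, 30)
  # mask "none" is the identity
  expect_identical(median_filter_map(m, "none"), m)
  # constant grids are unchanged by any mask
  for (mask in c(3, 5, 9, 11, 23)) {
    expect_equal(median_filter_map(matrix(7, 25, 25), mask),
                 matrix(7, 25, 25))
  }
  # a lone spike is erased by the 3x3 filter
  z <- matrix(0, 15, 15); z[8, 8] <- 50
  expect_equal(median_filter_map(z, 3), matrix(0, 15, 15))
  # exact equality with the double-loop oracle on random grids
  for (s in 1:3) {
    set.seed(s)
    m <- matrix(rnorm(20 * 30), 20, 30)
    expect_identical(median_filter_map(m, 3), oracle_median_filter(m, 3))
    expect_identical(median_filter_map(m, 5), oracle_median_filter(m, 5))
  }
  expect_error(median_filter_map(m, 7), "allowed")
})
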