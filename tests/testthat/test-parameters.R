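test_that("unit conversion matches the published worked examples exactly", {
  expect_equal(convert_units(29, "temporal", decimals = 1), 6.7)
  expect_equal(convert_units(96, "temporal", decimals = 1), 22.2)
  expect_equal(convert_units(323, "temporal", decimals = 1), 74.6)
  expect_equal(convert_units(66.6, "spatial", decimals = 1), 10.0)
  expect_equal(convert_units(20.7, "spatial", decimals = 1), 3.1)
  expect_equal(convert_units(0.2, "spatial", decimals = 2), 0.03)
  expect_equal(convert_units(0, "spatial"), 0)
  expect_equal(convert_units(0, "temporal"), 0)
  # custom calibration flows through linearly
  expect_equal(convert_units(10, "spatial", pixel_pitch_mm = 0.2), 2)
  expect_error(convert_units(1, "sideways"))
  expect_error(convert_units(1, "spatial", pixel_pitch_mm = -1), "positive")
})

test_that("applanation detection handles degenerate geometries", {
  n <- 30; w <- 400
  # static, perfectly flat contour: applanation 1 at frame 0 with velocity 0
  f <- field_from_matrix(matrix(90, n, w), baseline_frames = 5, margin = 40)
  cs <- contours_from_matrix(matrix(90, n, w))
  app <- detect_applanations(f, cs)
  expect_equal(app$applanation1$time_frames, 0L)
  expect_equal(app$applanation1$velocity_px_per_frame, 0)

  # rigid translation of a curved contour never flattens
  arc <- 60 + 0.0015 * ((1:w) - w / 2)^2
  oc <- matrix(rep(arc, each = n), n, w)
  oc[16:n, ] <- oc[16:n, ] + 4
  f <- field_from_matrix(oc, baseline_frames = 5, margin = 40)
  app <- detect_applanations(f, contours_from_matrix(oc))
  expect_null(app$applanation1)
  expect_null(app$applanation2)
})

test_that("highest concavity finds crests, distance, and the circle radius", {
  n <- 20; w <- 450
  x <- 1:w
  # concave circular arc of radius 180 between crests at columns 201/377
  # (0-based 200/376), rendered as an exact piecewise contour
  cl <- 201; cr <- 377; cc <- (cl + cr) / 2; R <- 180
  seg <- x >= cl & x <= cr
  y0 <- rep(70, w)
  ydef <- y0
  ydef[seg] <- 70 + sqrt(R^2 - ((x[seg] - cc))^2) - sqrt(R^2 - (cl - cc)^2)
  ydef[!seg] <- 70 + 0.02 * abs(x[!seg] - ifelse(x[!seg] < cl, cl, cr))
  oc <- matrix(rep(y0, each = n), n, w)
  oc[12, ] <- ydef  # deepest deformation at frame 11 (0-based)
  f <- field_from_matrix(oc, baseline_frames = 5, margin = 40)
  hc <- highest_concavity(f, contours_from_matrix(oc))
  expect_equal(hc$time_frames, 11L)
  expect_equal(hc$peak_distance_px, 176)
  expect_equal(hc$radius_px, 180, tolerance = 0.01)

  # perfectly straight central contour: no crests, absent distance
  f <- field_from_matrix(matrix(90, n, w), baseline_frames = 5, margin = 40)
  hc <- highest_concavity(f, contours_from_matrix(matrix(90, n, w)))
  expect_true(is.na(hc$peak_distance_px))

  # circle fit flags collinear points as infinite radius
  expect_equal(corvistk:::circle_fit_radius(1:50, rep(3, 50)), Inf)
  expect_equal(corvistk:::circle_fit_radius(1:50, 2 * (1:50) + 1), Inf)
})

test_that("amplitude metrics cover zero fields and mirrored signs", {
  f <- field_from_matrix(matrix(80, 25, 120), baseline_frames = 5, margin = 20)
  am <- amplitude_metrics(f)
  expect_equal(am$max_deformation_px, 0)
  expect_equal(am$max_cornea_deformation_px, 0)
  expect_equal(am$max_eyeball_amplitude_px, 0)
  expect_equal(am$absolute_cornea_reaction_px, 0)
  expect_equal(am$deformation_diff_min_px, 0)
  expect_equal(am$deformation_diff_max_px, 0)

  # sign symmetry: negating the corneal field swaps min/max and preserves
  # the absolute reaction
  set.seed(3)
  oc <- matrix(80 + rnorm(25 * 120), 25, 120)
  f <- field_from_matrix(oc, baseline_frames = 5, margin = 20)
  am <- amplitude_metrics(f)
  fneg <- f; fneg$cornea <- -f$cornea
  amn <- amplitude_metrics(fneg)
  expect_equal(amn$absolute_cornea_reaction_px, am$absolute_cornea_reaction_px)
  expect_equal(amn$deformation_diff_min_px, -am$deformation_diff_max_px)
  expect_equal(amn$max_cornea_deformation_px, max(-f$cornea))
})

test_that("corneal length change matches quadrature and ignores translation", {
  n <- 12; w <- 300
  base <- rep(60, w)
  oc <- matrix(rep(base, each = n), n, w)
  cs <- contours_from_matrix(oc)
  dl <- corneal_length_change(cs, base)
  expect_lt(max(abs(dl)), 1e-9)

  # rigid translation leaves the arc length unchanged
  oc2 <- oc + 7.3
  expect_lt(max(abs(corneal_length_change(contours_from_matrix(oc2), base + 7.3))),
            1e-9)

  # a Gaussian deepening changes the length as the quadrature oracle says
  A <- 25; sig <- 35; c0 <- 150
  gauss <- function(x) A * exp(-(x - c0)^2 / (2 * sig^2))
  oc3 <- oc
  oc3[n, ] <- 60 + gauss(1:w)
  dl <- corneal_length_change(contours_from_matrix(oc3), base)
  truth <- oracle_arc_length(function(x) -A * (x - c0) / sig^2 *
                               exp(-(x - c0)^2 / (2 * sig^2)), 1, w) - (w - 1)
  expect_lt(abs(dl[n] - truth) / truth, 0.01)
})

test_that("ratios follow their documented conventions", {
  r <- compute_ratios(60, c(0, 5, 12), rep(100, 50))
  expect_equal(r$ratio_amp_over_length, 5)
  expect_equal(r$ratio_reaction_over_static, 0.6)
  r0 <- compute_ratios(0, c(0, 0), rep(100, 50))
  expect_equal(r0$ratio_amp_over_length, 0)
  expect_equal(r0$ratio_reaction_over_static, 0)
  # undefined when the deformation is nonzero but the length never changes
  rna <- compute_ratios(10, c(0, 0), rep(100, 50))
  expect_true(is.na(rna$ratio_amp_over_length))
})

test_that("vibration metrics count supra-threshold frames", {
  f <- field_from_matrix(matrix(50, 40, 60), baseline_frames = 5, margin = 10)
  vm <- vibration_metrics(f)
  expect_equal(vm$max_vibration_amplitude_px, 0)
  expect_equal(vm$vibration_duration_frames, 0L)

  f$vibration <- matrix(0, 40, 60)
  f$vibration[10:20, 30] <- c(rep(0.8, 6), rep(0.3, 5))
  vm <- vibration_metrics(f, threshold_px = 0.5)
  expect_equal(vm$max_vibration_amplitude_px, 0.8)
  expect_equal(vm$vibration_duration_frames, 6L)
  # threshold above the maximum: zero duration
  vm <- vibration_metrics(f, threshold_px = 1)
  expect_equal(vm$vibration_duration_frames, 0L)
})

test_that("pipeline vibration duration tracks the ground-truth envelope", {
  cfg <- small_config(noise_sigma = 1, vib_frequency_hz = 300,
                      vib_amplitude_px = 1.0, vib_start = 18, vib_end = 50,
                      vib_taper = 6)
  r <- render_sequence(cfg)
  an <- analyze_sequence(r$sequence, baseline_frames = 5, scleral_margin = 30)
  truth_dur <- sum(apply(abs(r$truth$vibration_true), 1, max) > 0.5)
  got <- an$report$vibration_duration_frames
  # the >100 Hz band also carries deformation-pulse energy, so the pipeline
  # may only over-count relative to the injected envelope
  expect_gte(got, truth_dur - 4)
})

test_that("asymmetry score is signed, thresholded, and mirror-antisymmetric", {
  # symmetric motion: zero score, undetermined side
  f <- field_from_matrix(matrix(rep(c(rep(70, 10), rep(73, 20)), 100), 30, 100,
                                byrow = FALSE), baseline_frames = 5, margin = 15)
  as1 <- asymmetry_and_side(f)
  expect_equal(as1$asymmetry_score_px, 0)
  expect_equal(as1$eye_side_label, "undetermined")

  # rendered tilt: left anchor about 3 px, right about 1 px at the peak
  cfg <- small_config(noise_sigma = 0, eyeball_left_px = 3, eyeball_right_px = 1)
  r <- render_sequence(cfg)
  an <- analyze_sequence(r$sequence, baseline_frames = 5, scleral_margin = 30)
  expect_equal(an$report$asymmetry_score_px, 2, tolerance = 0.15)
  expect_equal(an$report$eye_side_label, "left")

  # mirroring the frames negates the score and flips the label
  mir <- r$sequence
  mir$frames <- mir$frames[, rev(seq_len(dim(mir$frames)[2])), ]
  anm <- analyze_sequence(mir, baseline_frames = 5, scleral_margin = 30)
  expect_equal(anm$report$asymmetry_score_px, -an$report$asymmetry_score_px,
               tolerance = 1e-6)
  expect_equal(anm$report$eye_side_label, "right")
})

test_that("curvature points report crest timing and local harmonic amplitude", {
  # straight contour: no crests, absent result
  n <- 30; w <- 300
  f <- field_from_matrix(matrix(90, n, w), baseline_frames = 5, margin = 30)
  sp <- fft_amplitude_map(f)
  expect_null(curvature_points(contours_from_matrix(matrix(90, n, w)), f, sp))

  # rendered sequence: curvature at the crest columns peaks near highest
  # concavity, when the flanks bend most
  cfg <- small_config(noise_sigma = 0)
  r <- render_sequence(cfg)
  an <- analyze_sequence(r$sequence, baseline_frames = 5, scleral_margin = 30)
  cp <- curvature_points(an$contours, an$field, an$spectrum)
  expect_length(cp$times_frames, 2L)
  # oracle: curvature schedule computed from the ground-truth contours
  h <- biomech_params()$w_curv
  for (s in 1:2) {
    c0 <- cp$columns[s] + 1L
    curv_true <- (r$truth$outer_true[, c0 - h] - 2 * r$truth$outer_true[, c0] +
                    r$truth$outer_true[, c0 + h]) / h^2
    expect_lte(abs(cp$times_frames[s] - (which.max(curv_true) - 1L)), 1)
  }
})

test_that("report assembly keeps event ordering and translation invariance", {
  cfg <- small_config(noise_sigma = 0, vib_frequency_hz = 400,
                      vib_amplitude_px = 0.3)
  r <- render_sequence(cfg)
  an <- analyze_sequence(r$sequence, baseline_frames = 5, scleral_margin = 30)
  rep1 <- an$report
  expect_lt(rep1$applanation1_time_frames, rep1$highest_concavity_time_frames)
  expect_lt(rep1$highest_concavity_time_frames, rep1$applanation2_time_frames)

  # adding a constant to every contour changes only the static-position ratio
  cs <- an$contours
  cs2 <- cs
  cs2$outer <- cs$outer + 11
  cs2$inner <- cs$inner + 11
  mk_report <- function(cset) {
    f <- compute_deformation_field(cset, 5)
    f <- split_eyeball_cornea(f, 30)
    f <- highpass_vibration(f, 100)
    compute_biomech_report(cset, f)
  }
  ra <- mk_report(cs); rb <- mk_report(cs2)
  same <- c("applanation1_time_frames", "applanation2_time_frames",
            "highest_concavity_time_frames", "peak_distance_px",
            "max_deformation_px", "max_cornea_deformation_px",
            "max_vibration_amplitude_px", "first_harmonic_hz",
            "asymmetry_score_px", "max_corneal_length_change_px")
  for (nm in same) expect_equal(rb[[nm]], ra[[nm]], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(rb$ratio_reaction_over_static,
                                ra$ratio_reaction_over_static)))
})
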