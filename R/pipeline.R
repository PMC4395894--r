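#' Assemble the full biomechanical report
#'
#' Runs every parameter extractor and collects the results in pixel/frame
#' units plus calibrated physical units (ms, mm; velocities mm/ms).
#'
#' @param contours a `contour_set`.
#' @param field a completed `deformation_field` (after
#'   [split_eyeball_cornea()] and [highpass_vibration()]).
#' @param spectrum the matching `spectral_map` (computed if `NULL`).
#' @param params a [biomech_params()].
#' @return A list of class `biomech_report`.
#' @export
compute_biomech_report <- function(contours, field, spectrum = NULL,
                                   params = biomech_params()) {
  if (is.null(spectrum)) spectrum <- fft_amplitude_map(field)
  app <- detect_applanations(field, contours, params)
  hc <- highest_concavity(field, contours)
  am <- amplitude_metrics(field)
  dl <- corneal_length_change(contours, field$baseline)
  ra <- compute_ratios(am$max_cornea_deformation_px, dl, field$baseline)
  vm <- vibration_metrics(field, params$vibration_threshold_px)
  fh <- first_harmonic(spectrum, params$harmonic_min_freq_hz)
  asym <- asymmetry_and_side(field, params$side_threshold)
  cp <- curvature_points(contours, field, spectrum, params)

  apex <- apex_column(field)
  pachy <- NA_real_
  if (all(is.finite(contours$inner[seq_len(field$baseline_frames), apex]))) {
    pachy <- mean(contours$inner[seq_len(field$baseline_frames), apex] -
                    contours$outer[seq_len(field$baseline_frames), apex])
  }

  px <- list(
    applanation1_time_frames = app$applanation1$time_frames %||% NA_real_,
    applanation1_length_px = app$applanation1$length_px %||% NA_real_,
    applanation1_velocity_px_per_frame =
      app$applanation1$velocity_px_per_frame %||% NA_real_,
    applanation2_time_frames = app$applanation2$time_frames %||% NA_real_,
    applanation2_length_px = app$applanation2$length_px %||% NA_real_,
    applanation2_velocity_px_per_frame =
      app$applanation2$velocity_px_per_frame %||% NA_real_,
    highest_concavity_time_frames = hc$time_frames,
    peak_distance_px = hc$peak_distance_px,
    radius_px = hc$radius_px,
    max_deformation_px = am$max_deformation_px,
    max_cornea_deformation_px = am$max_cornea_deformation_px,
    max_eyeball_amplitude_px = am$max_eyeball_amplitude_px,
    deformation_diff_min_px = am$deformation_diff_min_px,
    deformation_diff_max_px = am$deformation_diff_max_px,
    absolute_cornea_reaction_px = am$absolute_cornea_reaction_px,
    max_corneal_length_change_px = max(dl),
    ratio_amp_over_length = ra$ratio_amp_over_length,
    ratio_reaction_over_static = ra$ratio_reaction_over_static,
    max_vibration_amplitude_px = vm$max_vibration_amplitude_px,
    vibration_duration_frames = vm$vibration_duration_frames,
    first_harmonic_hz = fh$frequency_hz,
    first_harmonic_amplitude_px = fh$amplitude_px,
    frequency_resolution_hz = fh$resolution_hz,
    curvature_point_times_frames = cp$times_frames %||% c(NA_real_, NA_real_),
    curvature_point_harmonic_amp_px = cp$harmonic_amp_px %||% c(NA_real_, NA_real_),
    asymmetry_score_px = asym$asymmetry_score_px,
    eye_side_label = asym$eye_side_label,
    pachymetry_px = pachy
  )

  pitch <- field$pixel_pitch_mm
  interval <- field$frame_interval_us
  sp <- function(v) convert_units(v, "spatial", pitch, interval)
  tm <- function(v) convert_units(v, "temporal", pitch, interval)
  converted <- list(
    applanation1_time_ms = tm(px$applanation1_time_frames),
    applanation1_length_mm = sp(px$applanation1_length_px),
    applanation1_velocity_mm_per_ms =
      px$applanation1_velocity_px_per_frame * pitch / (interval / 1000),
    applanation2_time_ms = tm(px$applanation2_time_frames),
    applanation2_length_mm = sp(px$applanation2_length_px),
    applanation2_velocity_mm_per_ms =
      px$applanation2_velocity_px_per_frame * pitch / (interval / 1000),
    highest_concavity_time_ms = tm(px$highest_concavity_time_frames),
    peak_distance_mm = sp(px$peak_distance_px),
    radius_mm = sp(px$radius_px),
    max_deformation_mm = sp(px$max_deformation_px),
    max_cornea_deformation_mm = sp(px$max_cornea_deformation_px),
    max_eyeball_amplitude_mm = sp(px$max_eyeball_amplitude_px),
    deformation_diff_min_mm = sp(px$deformation_diff_min_px),
    deformation_diff_max_mm = sp(px$deformation_diff_max_px),
    absolute_cornea_reaction_mm = sp(px$absolute_cornea_reaction_px),
    max_corneal_length_change_mm = sp(px$max_corneal_length_change_px),
    max_vibration_amplitude_mm = sp(px$max_vibration_amplitude_px),
    vibration_duration_ms = tm(px$vibration_duration_frames),
    first_harmonic_amplitude_mm = sp(px$first_harmonic_amplitude_px),
    curvature_point_times_ms = tm(px$curvature_point_times_frames),
    curvature_point_harmonic_amp_mm = sp(px$curvature_point_harmonic_amp_px),
    asymmetry_score_mm = sp(px$asymmetry_score_px),
    pachymetry_mm = sp(px$pachymetry_px)
  )

  structure(c(px,
              list(corneal_length_change_px = dl,
                   converted = converted,
                   calibration = list(pixel_pitch_mm = pitch,
                                      frame_interval_us = interval),
                   conventions = list(
                     ratio_amp_over_length = "max cornea deformation / max arc-length change",
                     ratio_reaction_over_static = "max cornea deformation / baseline apex row",
                     absolute_cornea_reaction = "max |cornea| over frames and columns",
                     pachymetry = "baseline inner-outer contour distance at the apex (not optical pachymetry)",
                     eye_side = "sign convention only; anatomical mapping unverified"),
                   schema_version = "biomech-report-1")),
            class = "biomech_report")
}

#' @export
print.biomech_report <- function(x, ...) {
  cat("Biomechanical report (px/frames; converted values in $converted):\n")
  cat(sprintf("  applanation 1 / 2 time: %s / %s frames\n",
              format(x$applanation1_time_frames), format(x$applanation2_time_frames)))
  cat(sprintf("  highest concavity time: %s frames\n",
              format(x$highest_concavity_time_frames)))
  cat(sprintf("  peak distance: %s px, radius: %s px\n",
              format(x$peak_distance_px), format(round(x$radius_px, 1))))
  cat(sprintf("  max deformation (full/cornea/eyeball): %.2f / %.2f / %.2f px\n",
              x$max_deformation_px, x$max_cornea_deformation_px,
              x$max_eyeball_amplitude_px))
  cat(sprintf("  first harmonic: %s Hz, %.3f px (resolution %.1f Hz)\n",
              format(round(x$first_harmonic_hz, 1)), x$first_harmonic_amplitude_px,
              x$frequency_resolution_hz))
  cat(sprintf("  vibration: max %.3f px, duration %d frames\n",
              x$max_vibration_amplitude_px, x$vibration_duration_frames))
  cat(sprintf("  asymmetry: %.3f px (%s eye)\n",
              x$asymmetry_score_px, x$eye_side_label))
  invisible(x)
}

#' One-row data frame of the scalar report fields
#'
#' @param x a `biomech_report`.
#' @param ... unused.
#' @export
as.data.frame.biomech_report <- function(x, ...) {
  scal <- x[!(names(x) %in% c("corneal_length_change_px", "converted",
                              "calibration", "conventions", "schema_version"))]
  scal$curvature_point_times_frames <- NULL
  scal$curvature_point_harmonic_amp_px <- NULL
  base <- as.data.frame(scal, stringsAsFactors = FALSE)
  base$curvature_point_time1_frames <- x$curvature_point_times_frames[1]
  base$curvature_point_time2_frames <- x$curvature_point_times_frames[2]
  base$curvature_point_harmonic_amp1_px <- x$curvature_point_harmonic_amp_px[1]
  base$curvature_point_harmonic_amp2_px <- x$curvature_point_harmonic_amp_px[2]
  conv <- x$converted
  conv$curvature_point_times_ms <- NULL
  conv$curvature_point_harmonic_amp_mm <- NULL
  cbind(base, as.data.frame(conv, stringsAsFactors = FALSE))
}

#' Analyse a frame sequence end to end
#'
#' Runs the complete pipeline: optional per-frame histogram equalization,
#' contour detection and repair, deformation-field construction,
#' eyeball/cornea split, >cutoff high-pass vibration extraction, optional
#' median filtering of the full deformation map (after which the
#' decomposition and every parameter are recomputed from the filtered map),
#' spectral map and biomechanical report.
#'
#' @param sequence a [frame_sequence()].
#' @param baseline_frames pre-puff frames averaged into the baseline
#'   (default 10).
#' @param scleral_margin columns per side anchoring the eyeball model
#'   (default 50).
#' @param cutoff_hz vibration high-pass cutoff (default 100).
#' @param median_mask `"none"` or 3/5/9/11/23; median filtering applied to
#'   the full deformation map before decomposition.
#' @param histogram_equalize equalize each frame first (default `FALSE`).
#' @param contour_cfg a [contour_config()].
#' @param params a [biomech_params()].
#' @return A list of class `corvis_analysis`: `contours`, `field`,
#'   `spectrum`, `report`, `source_id` and the configuration in effect.
#' @export
analyze_sequence <- function(sequence, baseline_frames = 10,
                             scleral_margin = 50, cutoff_hz = 100,
                             median_mask = "none",
                             histogram_equalize = FALSE,
                             contour_cfg = contour_config(),
                             params = biomech_params()) {
  stopifnot(inherits(sequence, "frame_sequence"))
  if (histogram_equalize) sequence <- equalize_histogram(sequence)
  contours <- detect_sequence_contours(sequence, contour_cfg)
  field <- compute_deformation_field(contours, baseline_frames,
                                     sequence$frame_interval_us,
                                     sequence$pixel_pitch_mm)
  if (!identical(median_mask, "none")) {
    field$full <- median_filter_map(field$full, median_mask)
    contours <- filtered_contours(contours, field)
  }
  field <- split_eyeball_cornea(field, scleral_margin)
  field <- highpass_vibration(field, cutoff_hz)
  spectrum <- fft_amplitude_map(field)
  report <- compute_biomech_report(contours, field, spectrum, params)
  structure(list(contours = contours, field = field, spectrum = spectrum,
                 report = report, source_id = sequence$source_id,
                 config = list(baseline_frames = baseline_frames,
                               scleral_margin = scleral_margin,
                               cutoff_hz = cutoff_hz,
                               median_mask = median_mask,
                               histogram_equalize = histogram_equalize,
                               contour_cfg = unclass(contour_cfg),
                               params = unclass(params))),
            class = "corvis_analysis")
}

# After median-filtering the deformation map, rebuild a contour set whose
# outer contour is baseline + filtered map so every downstream parameter is
# recomputed from the filtered data.
filtered_contours <- function(contours, field) {
  contours$outer <- sweep(field$full, 2, field$baseline, `+`)
  contours
}

#' @export
print.corvis_analysis <- function(x, ...) {
  cat(sprintf("corvis_analysis of %s\n", x$source_id))
  print(x$report)
  invisible(x)
}
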