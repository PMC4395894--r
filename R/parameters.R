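# Biomechanical parameter extraction: everything the report table holds is
# computed from the contour set, the deformation decomposition and the
# spectral map. All times are 0-based frame indices, all lengths pixels;
# convert_units() maps them to ms / mm.

#' Analysis parameter defaults
#'
#' @param flatness_tol max deviation (px) from the least-squares line for a
#'   column run to count as flat (default 0.4).
#' @param min_applanation_len_px flat-run length (columns) that defines an
#'   applanation event (default 60).
#' @param applanation_halfwidth half-width (columns) of the apex-centred
#'   window searched for flat runs (default 150).
#' @param contour_smooth_w boxcar width (columns) applied to the contour
#'   before the flatness test; stabilises event frames under sensor noise
#'   (odd, default 5).
#' @param side_threshold asymmetry score (px) below which the eye side is
#'   undetermined (default 0.5).
#' @param vibration_threshold_px per-frame vibration amplitude that counts
#'   toward the vibration duration (default 0.5).
#' @param w_curv column offset of the discrete second difference used as the
#'   curvature measure at the flanking peaks (default 10).
#' @param harmonic_min_freq_hz lowest frequency considered a harmonic
#'   (default 100).
#' @return A list of class `biomech_params`.
#' @export
biomech_params <- function(flatness_tol = 0.4, min_applanation_len_px = 60,
                           applanation_halfwidth = 150, contour_smooth_w = 5,
                           side_threshold = 0.5, vibration_threshold_px = 0.5,
                           w_curv = 10, harmonic_min_freq_hz = 100) {
  structure(list(flatness_tol = flatness_tol,
                 min_applanation_len_px = min_applanation_len_px,
                 applanation_halfwidth = applanation_halfwidth,
                 contour_smooth_w = contour_smooth_w,
                 side_threshold = side_threshold,
                 vibration_threshold_px = vibration_threshold_px,
                 w_curv = w_curv,
                 harmonic_min_freq_hz = harmonic_min_freq_hz),
            class = "biomech_params")
}

# Boxcar smoothing across columns with replicated ends.
boxcar <- function(y, w) {
  if (w <= 1L) return(y)
  r <- (w - 1) %/% 2
  yp <- c(rep(y[1], r), y, rep(y[length(y)], r))
  as.numeric(stats::filter(yp, rep(1 / w, w), sides = 2))[(r + 1):(r + length(y))]
}

# Longest run of consecutive columns of y whose values stay within `tol` of
# the run's own least-squares line. Forward two-pointer sweep; assumes
# flatness is hereditary (sub-runs of a flat run are flat), which holds for
# the smooth contours seen here.
max_flat_run <- function(y, tol) {
  n <- length(y)
  run_flat <- function(i, j) {
    len <- j - i + 1
    if (len < 3L) return(TRUE)
    xs <- seq_len(len)
    ys <- y[i:j]
    mx <- (len + 1) / 2
    my <- mean(ys)
    vx <- sum((xs - mx)^2)
    b <- sum((xs - mx) * (ys - my)) / vx
    max(abs(ys - my - b * (xs - mx))) < tol
  }
  best_len <- 0L; best_start <- NA_integer_
  i <- 1L; j <- 1L
  while (j <= n) {
    if (run_flat(i, j)) {
      if (j - i + 1L > best_len) { best_len <- j - i + 1L; best_start <- i }
      j <- j + 1L
    } else {
      i <- i + 1L
      if (i > j) j <- i
    }
  }
  list(length = best_len, start = best_start)
}

# Apex column: where the corneal deformation peaks (the air puff is aimed at
# the apex); for an undeformed field, the highest point of the baseline.
apex_column <- function(field) {
  if (!is.null(field$cornea) && max(field$cornea) > 0) {
    idx <- which(field$cornea == max(field$cornea), arr.ind = TRUE)[1, ]
    return(as.integer(idx[[2]]))
  }
  which.min(field$baseline)
}

#' Detect the two applanation events
#'
#' Per frame, the applanation length is the longest run of consecutive
#' columns (within an apex-centred window) whose outer contour stays within
#' `flatness_tol` px of its own least-squares line. Applanation 1 is the
#' first frame at or before highest concavity whose flat run reaches
#' `min_applanation_len_px`; applanation 2 is the first such frame after
#' highest concavity. The velocity is the central-difference rate of the apex
#' displacement at the event frame (px/frame).
#'
#' @param field a completed `deformation_field`.
#' @param contours the `contour_set` the field was computed from.
#' @param params a [biomech_params()].
#' @return List with `applanation1`, `applanation2` (each `NULL` when absent,
#'   else `time_frames` (0-based), `length_px`, `velocity_px_per_frame`) and
#'   the per-frame `flat_lengths`.
#' @export
detect_applanations <- function(field, contours, params = biomech_params()) {
  stopifnot(!is.null(field$cornea))
  n <- nrow(field$full); w <- ncol(field$full)
  apex <- apex_column(field)
  win <- max(1L, apex - params$applanation_halfwidth):
         min(w, apex + params$applanation_halfwidth)
  lens <- integer(n)
  for (t in seq_len(n)) {
    y <- boxcar(contours$outer[t, win], params$contour_smooth_w)
    lens[t] <- max_flat_run(y, params$flatness_tol)$length
  }
  t_peak <- which.max(field$cornea[, apex])
  apex_trace <- field$full[, apex]
  vel <- function(t) {
    lo <- max(1L, t - 1L); hi <- min(n, t + 1L)
    (apex_trace[hi] - apex_trace[lo]) / (hi - lo)
  }
  hit1 <- which(lens[seq_len(t_peak)] >= params$min_applanation_len_px)
  hit2 <- which(lens >= params$min_applanation_len_px)
  hit2 <- hit2[hit2 > t_peak]
  ev <- function(t) list(time_frames = t - 1L, length_px = as.numeric(lens[t]),
                         velocity_px_per_frame = vel(t))
  list(
    applanation1 = if (length(hit1)) ev(hit1[1]) else NULL,
    applanation2 = if (length(hit2)) ev(hit2[1]) else NULL,
    flat_lengths = lens
  )
}

# Algebraic (Kasa) circle fit; returns radius (px) or Inf when degenerate.
circle_fit_radius <- function(x, y) {
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3L) return(Inf)
  co <- unname(qr.coef(qrA, b))
  cx <- co[1] / 2; cy <- co[2] / 2
  r2 <- co[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(Inf)
  r <- sqrt(r2)
  if (r > 1e6) Inf else r
}

#' Highest concavity frame, peak distance and concave radius
#'
#' The highest-concavity time is the frame of maximal corneal deformation at
#' the apex column. At that frame the two flanking crests (local minima of
#' the outer-contour row on each side of the apex) give the peak distance,
#' and an algebraic least-squares circle fit to the outer contour between the
#' crests gives the radius of the concave central arc (reported positive; a
#' straight segment is flagged with an infinite radius).
#'
#' @param field a completed `deformation_field`.
#' @param contours the matching `contour_set`.
#' @return List with `time_frames` (0-based), `peak_distance_px` (`NA` when
#'   the crests are not found), `radius_px` (may be `Inf`) and `peak_cols`
#'   (0-based pair).
#' @export
highest_concavity <- function(field, contours) {
  stopifnot(!is.null(field$cornea))
  apex <- apex_column(field)
  w <- ncol(field$full)
  t_star <- which.max(field$cornea[, apex])
  y <- contours$outer[t_star, ]
  left <- which.min(y[seq_len(max(1L, apex - 1L))])
  right <- apex + which.min(y[(apex + 1L):w])
  crest_ok <- left > 1L && left < apex && right > apex && right < w
  pd <- if (crest_ok) right - left else NA_real_
  radius <- NA_real_
  if (crest_ok) {
    seg <- left:right
    radius <- circle_fit_radius(seg - 1, y[seg])
  }
  list(time_frames = t_star - 1L,
       peak_distance_px = as.numeric(pd),
       radius_px = radius,
       peak_cols = if (crest_ok) c(left, right) - 1L else NULL)
}

#' Amplitude metrics of the decomposition
#'
#' @param field a completed `deformation_field`.
#' @return List with `max_deformation_px` (max of the full field),
#'   `max_cornea_deformation_px`, `max_eyeball_amplitude_px` (max over frames
#'   of the mean eyeball displacement), `deformation_diff_min_px` /
#'   `deformation_diff_max_px` (extremes of the frame-to-frame difference of
#'   the corneal component) and `absolute_cornea_reaction_px` (max |cornea|).
#' @export
amplitude_metrics <- function(field) {
  stopifnot(!is.null(field$cornea), !is.null(field$eyeball))
  n <- nrow(field$cornea)
  d <- field$cornea[-1L, , drop = FALSE] - field$cornea[-n, , drop = FALSE]
  list(max_deformation_px = max(field$full),
       max_cornea_deformation_px = max(field$cornea),
       max_eyeball_amplitude_px = max(rowMeans(field$eyeball)),
       deformation_diff_min_px = min(d),
       deformation_diff_max_px = max(d),
       absolute_cornea_reaction_px = max(abs(field$cornea)))
}

#' Corneal arc-length change over time
#'
#' Polyline arc length of the outer contour (unit column spacing) over a
#' column window, minus the arc length of the static baseline contour.
#' Rigid translations leave it at zero.
#'
#' @param contours a `contour_set`.
#' @param baseline static outer contour (from the `deformation_field`).
#' @param window integer columns used (1-based; default the full width).
#' @return Numeric vector, one arc-length change (px) per frame.
#' @export
corneal_length_change <- function(contours, baseline, window = NULL) {
  w <- contours$width
  if (is.null(window)) window <- seq_len(w)
  arc <- function(y) sum(sqrt(1 + diff(y)^2))
  l0 <- arc(baseline[window])
  vapply(seq_len(contours$n_frames),
         function(t) arc(contours$outer[t, window]) - l0, numeric(1))
}

#' Amplitude/length and reaction/static ratios
#'
#' `ratio_amp_over_length` divides the maximum corneal deformation by the
#' maximum corneal arc-length change; `ratio_reaction_over_static` divides it
#' by the baseline apex row position. Both denominators are this package's
#' documented conventions. A zero-deformation field yields 0 for both; a
#' vanishing denominator with nonzero deformation yields `NA` (undefined).
#'
#' @param max_cornea_px maximum corneal deformation (px).
#' @param length_change_px vector from [corneal_length_change()].
#' @param baseline static outer contour.
#' @return List with the two ratios.
#' @export
compute_ratios <- function(max_cornea_px, length_change_px, baseline) {
  if (max_cornea_px == 0)
    return(list(ratio_amp_over_length = 0, ratio_reaction_over_static = 0))
  ml <- max(length_change_px)
  apex_row <- baseline[which.min(baseline)]
  list(
    ratio_amp_over_length = if (ml > 0) max_cornea_px / ml else NA_real_,
    ratio_reaction_over_static =
      if (apex_row > 0) max_cornea_px / apex_row else NA_real_
  )
}

#' Vibration amplitude and duration
#'
#' @param field a `deformation_field` with `vibration` filled.
#' @param threshold_px per-frame amplitude that counts toward the duration.
#' @return List with `max_vibration_amplitude_px` (max |vibration|) and
#'   `vibration_duration_frames` (frames whose column-max |vibration| exceeds
#'   the threshold).
#' @export
vibration_metrics <- function(field, threshold_px = 0.5) {
  stopifnot(!is.null(field$vibration))
  per_frame <- apply(abs(field$vibration), 1L, max)
  list(max_vibration_amplitude_px = max(per_frame),
       vibration_duration_frames = sum(per_frame > threshold_px))
}

#' Scleral reaction asymmetry and eye-side label
#'
#' The asymmetry score is the difference between the left and right scleral
#' anchors of the eyeball model, taken at the frame where its magnitude
#' peaks (so mirroring the image negates the score). Which anatomical side a
#' positive score denotes is a labelling convention, not a measurement.
#'
#' @param field a `deformation_field` after [split_eyeball_cornea()].
#' @param side_threshold |score| below this is labelled `"undetermined"`.
#' @return List with `asymmetry_score_px` and `eye_side_label`.
#' @export
asymmetry_and_side <- function(field, side_threshold = 0.5) {
  stopifnot(!is.null(field$anchors_left))
  d <- field$anchors_left - field$anchors_right
  score <- d[which.max(abs(d))]
  label <- if (score > side_threshold) "left"
           else if (score < -side_threshold) "right"
           else "undetermined"
  list(asymmetry_score_px = score, eye_side_label = label)
}

# Largest local spectral maximum at one column (same rule as first_harmonic).
harmonic_at_column <- function(spectrum, col, min_freq_hz = 100) {
  a <- spectrum$amplitude[, col]
  nk <- length(a)
  eligible <- spectrum$freqs >= min_freq_hz
  up <- a[c(1L, seq_len(nk - 1L))]
  dn <- a[c(seq_len(nk)[-1L], nk)]
  loc <- a > up & a >= dn & eligible
  loc[1L] <- FALSE
  if (any(loc)) {
    cand <- which(loc)
    k <- cand[which.max(vapply(cand, function(q) spectral_prominence(a, q),
                               numeric(1)))]
  } else {
    am <- ifelse(eligible, a, -Inf)
    k <- which.max(am)
  }
  list(frequency_hz = spectrum$freqs[k], amplitude_px = a[k])
}

#' Curvature-point events at the flanking crests
#'
#' For each of the two crest columns found at highest concavity, returns the
#' frame where the local curvature (discrete second difference of the outer
#' contour across columns at offset `w_curv`) peaks, and the first-harmonic
#' amplitude of the corneal spectrum at that column.
#'
#' @param contours a `contour_set`.
#' @param field a completed `deformation_field`.
#' @param spectrum the matching `spectral_map`.
#' @param params a [biomech_params()].
#' @return `NULL` when the crests are absent; else a list with
#'   `times_frames` (0-based pair), `harmonic_amp_px` (pair) and
#'   `columns` (0-based pair).
#' @export
curvature_points <- function(contours, field, spectrum,
                             params = biomech_params()) {
  hc <- highest_concavity(field, contours)
  if (is.null(hc$peak_cols)) return(NULL)
  h <- params$w_curv
  w <- contours$width
  cols <- hc$peak_cols + 1L
  times <- integer(2); amps <- numeric(2)
  for (s in 1:2) {
    c0 <- min(max(cols[s], h + 1L), w - h)
    curv <- (contours$outer[, c0 - h] - 2 * contours$outer[, c0] +
               contours$outer[, c0 + h]) / h^2
    times[s] <- which.max(curv) - 1L
    ha <- harmonic_at_column(spectrum, c0, params$harmonic_min_freq_hz)
    amps[s] <- ha$amplitude_px
  }
  list(times_frames = times, harmonic_amp_px = amps, columns = hc$peak_cols)
}

#' Convert pixel/frame values to physical units
#'
#' Spatial values are multiplied by the pixel pitch (mm); temporal values by
#' the frame interval (ms). Rounding, when requested, is half away from zero
#' at the stated number of decimals — the convention used for all displayed
#' physical values.
#'
#' @param value numeric value(s) in px (spatial) or frames (temporal).
#' @param axis `"spatial"` or `"temporal"`.
#' @param pixel_pitch_mm mm per pixel (default 0.15).
#' @param frame_interval_us microseconds per frame (default 231).
#' @param decimals display precision; `NULL` leaves the value unrounded.
#' @return Converted value(s) in mm or ms.
#' @export
#' @examples
#' convert_units(96, "temporal", decimals = 1)   # 22.2 ms
#' convert_units(66.6, "spatial", decimals = 1)  # 10.0 mm
convert_units <- function(value, axis = c("spatial", "temporal"),
                          pixel_pitch_mm = 0.15, frame_interval_us = 231,
                          decimals = NULL) {
  axis <- match.arg(axis)
  if (pixel_pitch_mm <= 0 || frame_interval_us <= 0)
    stop("calibration must be positive")
  out <- if (axis == "spatial") value * pixel_pitch_mm
         else value * frame_interval_us / 1000
  if (!is.null(decimals)) out <- round_half_away(out, decimals)
  out
}
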