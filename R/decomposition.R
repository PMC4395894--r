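#' Build the deformation field from detected contours
#'
#' The static baseline ("constant component", the cornea before deformation)
#' is the per-column mean of the outer contour over the first
#' `baseline_frames` frames; the full deformation is the outer contour minus
#' that baseline (positive = the contour moves to larger rows, i.e. inward
#' under the air puff). The difference-from-static view is exactly `full`.
#'
#' @param contours a `contour_set` from [detect_sequence_contours()].
#' @param baseline_frames number of pre-puff frames averaged into the
#'   baseline (default 10; must be >= 1 and < n_frames).
#' @param frame_interval_us,pixel_pitch_mm calibration carried through to the
#'   report stage.
#' @return A `deformation_field` with `baseline` and `full` filled; pass it
#'   through [split_eyeball_cornea()] and [highpass_vibration()] to complete
#'   the decomposition.
#' @export
compute_deformation_field <- function(contours, baseline_frames = 10,
                                      frame_interval_us = 231,
                                      pixel_pitch_mm = 0.15) {
  stopifnot(inherits(contours, "contour_set"))
  n <- contours$n_frames
  if (baseline_frames < 1 || baseline_frames >= n)
    stop("baseline_frames must be in [1, n_frames)")
  baseline <- colMeans(contours$outer[seq_len(baseline_frames), , drop = FALSE])
  full <- sweep(contours$outer, 2, baseline)
  structure(list(baseline = baseline, full = full,
                 eyeball = NULL, cornea = NULL,
                 cornea_low = NULL, vibration = NULL,
                 anchors_left = NULL, anchors_right = NULL,
                 baseline_frames = baseline_frames,
                 scleral_margin = NA_integer_, cutoff_hz = NA_real_,
                 frame_interval_us = frame_interval_us,
                 pixel_pitch_mm = pixel_pitch_mm),
            class = "deformation_field")
}

#' Split the full deformation into eyeball and corneal components
#'
#' The whole-eye (eyeball) response is modelled as a per-frame linear field
#' anchored at the two scleral margins: the left anchor `L[t]` is the mean of
#' the full deformation over the `scleral_margin` leftmost columns, the right
#' anchor `R[t]` over the rightmost, and the eyeball field interpolates
#' linearly between the two anchor centres (rigid retraction plus tilt). The
#' corneal deformation is the exact remainder `full - eyeball`.
#'
#' @param field a `deformation_field` with `full` filled.
#' @param scleral_margin number of columns per side used as anchors
#'   (default 50; both margins together must stay below the width).
#' @return The field with `eyeball`, `cornea` and the anchor series filled.
#' @export
split_eyeball_cornea <- function(field, scleral_margin = 50) {
  stopifnot(inherits(field, "deformation_field"))
  w <- ncol(field$full)
  m <- scleral_margin
  if (2 * m >= w) stop("scleral_margin too large for image width")
  L <- rowMeans(field$full[, seq_len(m), drop = FALSE])
  R <- rowMeans(field$full[, (w - m + 1):w, drop = FALSE])
  xl <- (1 + m) / 2
  xr <- w - (m - 1) / 2
  wgt <- (seq_len(w) - xl) / (xr - xl)
  field$eyeball <- outer(R - L, wgt) + L
  field$cornea <- field$full - field$eyeball
  field$anchors_left <- L
  field$anchors_right <- R
  field$scleral_margin <- m
  field
}

#' Extract the high-frequency vibration component
#'
#' Per column, the corneal deformation is Fourier transformed in time and all
#' bins below `cutoff_hz` (including DC) are zeroed; the inverse transform is
#' the vibration component (zero mean, zero phase distortion, exactly
#' real-valued by conjugate symmetry). `cornea_low = cornea - vibration`
#' holds element-wise by construction.
#'
#' @param field a `deformation_field` with `cornea` filled.
#' @param cutoff_hz high-pass cutoff (default 100); must be below Nyquist.
#' @return The field with `vibration` and `cornea_low` filled.
#' @export
highpass_vibration <- function(field, cutoff_hz = 100) {
  stopifnot(inherits(field, "deformation_field"), !is.null(field$cornea))
  n <- nrow(field$cornea)
  fs <- 1e6 / field$frame_interval_us
  if (cutoff_hz >= fs / 2)
    stop(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)", cutoff_hz, fs / 2))
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  keep <- freq >= cutoff_hz
  X <- stats::mvfft(field$cornea)
  X[!keep, ] <- 0
  field$vibration <- Re(stats::mvfft(X, inverse = TRUE)) / n
  field$cornea_low <- field$cornea - field$vibration
  field$cutoff_hz <- cutoff_hz
  field
}

#' Temporal amplitude spectrum of the corneal deformation, per column
#'
#' Single-sided FFT amplitude of the corneal deformation time series at every
#' column: `(2/N)|X_k|` for interior bins, `(1/N)|X_k|` for DC (and the
#' Nyquist bin when N is even), with bin centres `k * fs / N`.
#'
#' @param field a `deformation_field` with `cornea` filled.
#' @return A `spectral_map`: matrix `amplitude` `[freq_bin, col]`, vector
#'   `freqs` (Hz), `n_frames` and `sampling_rate_hz`.
#' @export
fft_amplitude_map <- function(field) {
  stopifnot(inherits(field, "deformation_field"), !is.null(field$cornea))
  n <- nrow(field$cornea)
  fs <- 1e6 / field$frame_interval_us
  nk <- floor(n / 2) + 1L
  X <- stats::mvfft(field$cornea)[seq_len(nk), , drop = FALSE]
  scale <- rep(2 / n, nk)
  scale[1] <- 1 / n
  if (n %% 2 == 0) scale[nk] <- 1 / n
  structure(list(amplitude = Mod(X) * scale,
                 freqs = (0:(nk - 1L)) * fs / n,
                 n_frames = n, sampling_rate_hz = fs),
            class = "spectral_map")
}

#' Dominant high-frequency spectral line (first harmonic)
#'
#' Identifies the corneal vibration's first harmonic as the most *prominent*
#' local maximum of the amplitude spectrum over all columns and bins at or
#' above `min_freq_hz`, where prominence is the amplitude above the median of
#' the nearby bins (a standard spectral-line picker). A plain global argmax
#' would instead return the air-puff deformation pulse's own spectral tail,
#' which decays through the >100 Hz band at amplitudes well above a
#' physiological vibration line; prominence separates a narrow line from
#' that smoothly decaying background. If no interior local maximum exists
#' the global maximum is returned.
#'
#' @param spectrum a `spectral_map`.
#' @param min_freq_hz lowest frequency considered (default 100).
#' @return List with `frequency_hz` (`NA` if the spectrum is all zero),
#'   `amplitude_px`, `column` (0-based) and `resolution_hz` (`fs/N`).
#' @export
first_harmonic <- function(spectrum, min_freq_hz = 100) {
  stopifnot(inherits(spectrum, "spectral_map"))
  a <- spectrum$amplitude
  eligible <- spectrum$freqs >= min_freq_hz
  if (!any(eligible)) stop("no frequency bin at or above min_freq_hz")
  res <- spectrum$sampling_rate_hz / spectrum$n_frames
  nk <- nrow(a)
  up <- a[c(1L, seq_len(nk - 1L)), , drop = FALSE]
  dn <- a[c(seq_len(nk)[-1L], nk), , drop = FALSE]
  local <- a > up & a >= dn
  local[1L, ] <- FALSE
  local[!eligible, ] <- FALSE
  if (any(local)) {
    cand <- which(local, arr.ind = TRUE)
    prom <- vapply(seq_len(nrow(cand)), function(q) {
      spectral_prominence(a[, cand[q, 2]], cand[q, 1])
    }, numeric(1))
    best <- cand[which.max(prom), ]
    k <- best[[1]]; col <- best[[2]]
  } else {
    masked <- a
    masked[!eligible, ] <- -Inf
    idx <- which(masked == max(masked), arr.ind = TRUE)[1, ]
    k <- idx[[1]]; col <- idx[[2]]
  }
  amp <- a[k, col]
  if (amp == 0)
    return(list(frequency_hz = NA_real_, amplitude_px = 0,
                column = NA_integer_, resolution_hz = res))
  list(frequency_hz = spectrum$freqs[k], amplitude_px = amp,
       column = as.integer(col) - 1L, resolution_hz = res)
}

# Amplitude of bin k above the median of the nearby bins (k +- 4, excluding
# k and its immediate neighbours): the height of a spectral line over the
# local background.
spectral_prominence <- function(v, k) {
  nb <- setdiff(max(2L, k - 4L):min(length(v), k + 4L), (k - 1L):(k + 1L))
  if (length(nb) == 0L) return(v[k])
  v[k] - stats::median(v[nb])
}

#' Median filtering of a deformation map
#'
#' Square median filter over the `[frame, col]` grid with replicated edges.
#' Only the mask sizes of the original tool are allowed: `"none"`, 3, 5, 9,
#' 11 or 23. Downstream parameters should be recomputed from the filtered
#' map (see [analyze_sequence()]'s `median_mask`).
#'
#' @param map numeric matrix `[frame, col]`.
#' @param mask `"none"` or one of 3, 5, 9, 11, 23.
#' @return The filtered matrix (the input itself for `"none"`).
#' @export
median_filter_map <- function(map, mask = "none") {
  allowed <- c(3, 5, 9, 11, 23)
  if (identical(mask, "none") || is.null(mask)) return(map)
  mask <- suppressWarnings(as.numeric(mask))
  if (is.na(mask) || !(mask %in% allowed))
    stop(sprintf("disallowed mask; allowed sizes: none, %s",
                 paste(allowed, collapse = ", ")))
  r <- (mask - 1) / 2
  p <- pad_replicate(map, r)
  n <- nrow(map); w <- ncol(map)
  out <- matrix(0, n, w)
  k2 <- mask * mask
  # chunk output rows to bound the gather matrix at ~50 MB
  chunk <- max(1L, floor(6e6 / (w * k2)))
  offs <- expand.grid(dr = 0:(2 * r), dc = 0:(2 * r))
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(n, i0 + chunk - 1L)
    rows <- i0:i1
    gath <- matrix(0, length(rows) * w, k2)
    for (q in seq_len(k2)) {
      gath[, q] <- as.vector(p[rows + offs$dr[q], (1:w) + offs$dc[q], drop = FALSE])
    }
    srt <- apply(gath, 1L, sort.int, method = "quick")
    mid <- (k2 + 1) / 2
    out[rows, ] <- matrix(srt[mid, ], length(rows), w)
  }
  out
}
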