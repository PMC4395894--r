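# Fixtures and independent oracles used across the suite. Everything is
# generated in code; nothing is read from disk.

# A small, fast synthetic configuration for property-style loops; any field
# can be overridden through ...
small_config <- function(seed = 1, ...) {
  defaults <- list(n_frames = 64, height = 120, width = 240,
                   arc_radius_px = 450, apex_row = 30,
                   corneal_thickness_px = 12,
                   bump_peak_px = 20, bump_sigma_px = 40,
                   bump_onset = 8, bump_peak_frame = 30, bump_offset = 55,
                   eyeball_left_px = 4, eyeball_right_px = 4,
                   eyeball_onset = 10, eyeball_peak_frame = 40,
                   eyeball_offset = 63,
                   noise_sigma = 2, seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# Build a contour_set directly from an outer-contour matrix [frame, col]
# (inner = outer + thickness), bypassing image rendering.
contours_from_matrix <- function(outer, thickness = 15, height = 200) {
  structure(list(outer = outer, inner = outer + thickness,
                 valid_outer = matrix(TRUE, nrow(outer), ncol(outer)),
                 valid_inner = matrix(TRUE, nrow(outer), ncol(outer)),
                 failed_frames = integer(0),
                 height = height, width = ncol(outer),
                 n_frames = nrow(outer)),
            class = "contour_set")
}

# Complete decomposition of a contour matrix with the given knobs.
field_from_matrix <- function(outer, baseline_frames = 5, margin = 30,
                              cutoff = 100, frame_interval_us = 231) {
  cs <- contours_from_matrix(outer)
  f <- compute_deformation_field(cs, baseline_frames,
                                 frame_interval_us = frame_interval_us)
  f <- split_eyeball_cornea(f, margin)
  highpass_vibration(f, cutoff)
}

# Brute-force oracle: integer argmax of the rising gradient of a single
# column, written with explicit loops and no shared code path beyond the
# arithmetic definition (3-tap binomial smoothing + central difference).
oracle_gradient_argmax <- function(column) {
  n <- length(column)
  s <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    s[i] <- (column[lo] + 2 * column[i] + column[hi]) / 4
  }
  g <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1) g[i] <- s[2] - s[1]
    else if (i == n) g[i] <- s[n] - s[n - 1]
    else g[i] <- (s[i + 1] - s[i - 1]) / 2
  }
  which.max(g) - 1L  # 0-based, ties to the smallest row
}

# Brute-force square median filter with replicated edges (double loop).
oracle_median_filter <- function(m, mask) {
  r <- (mask - 1) / 2
  n <- nrow(m); w <- ncol(m)
  out <- matrix(0, n, w)
  for (i in seq_len(n)) {
    for (j in seq_len(w)) {
      ri <- pmin(pmax((i - r):(i + r), 1), n)
      ci <- pmin(pmax((j - r):(j + r), 1), w)
      out[i, j] <- median(m[ri, ci])
    }
  }
  out
}

# Analytic arc length of y = f(x) over [a, b] by adaptive quadrature.
oracle_arc_length <- function(f_prime, a, b) {
  integrate(function(x) sqrt(1 + f_prime(x)^2), a, b,
            rel.tol = 1e-10)$value
}
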