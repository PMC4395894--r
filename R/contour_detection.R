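#' Contour detection configuration
#'
#' Tunable parameters of the per-column gradient-peak contour detector. The
#' gradient operator is a central finite difference applied to column profiles
#' pre-smoothed with a 3-tap binomial kernel; only the peak magnitude and the
#' inner-edge search window are thresholded.
#'
#' @param min_gradient minimum gradient magnitude (grey levels/px) for a peak
#'   to count as an edge (default 8).
#' @param max_thickness_px inner edge is sought within this many rows below
#'   the outer edge (default 40).
#' @param w_med window of the running median used to flag contour outliers
#'   (odd, default 11).
#' @param jump_tol deviation from the running median (px) beyond which a
#'   column is treated as an outlier and repaired (default 10).
#' @param max_failed_frames how many all-failed frames may be interpolated in
#'   time before the sequence is rejected (default 5).
#' @return A list of class `contour_config`.
#' @export
contour_config <- function(min_gradient = 8, max_thickness_px = 40,
                           w_med = 11, jump_tol = 10, max_failed_frames = 5) {
  structure(list(min_gradient = min_gradient,
                 max_thickness_px = max_thickness_px,
                 w_med = w_med, jump_tol = jump_tol,
                 max_failed_frames = max_failed_frames),
            class = "contour_config")
}

# Parabolic sub-pixel refinement of a peak at index i of g (1-based);
# returns the 0-based sub-pixel position, clamped to +-0.5 px of the peak.
refine_parabolic <- function(g, i) {
  n <- length(g)
  if (i <= 1L || i >= n) return(i - 1)
  denom <- g[i - 1] - 2 * g[i] + g[i + 1]
  delta <- if (denom == 0) 0 else 0.5 * (g[i - 1] - g[i + 1]) / denom
  (i - 1) + max(-0.5, min(0.5, delta))
}

#' Locate the strongest brightness-gradient step in one column profile
#'
#' Finds the largest signed finite-difference gradient over `search_range`
#' (`rising`: dark-to-bright going down the column, `falling`: bright-to-dark)
#' on the binomially smoothed profile, refines it to sub-pixel position by
#' parabolic interpolation of the gradient peak and its neighbours, and
#' rejects peaks weaker than `min_gradient`. Ties go to the smallest row.
#'
#' @param column numeric intensity profile (length >= 3).
#' @param search_range integer vector of candidate 0-based rows (default all).
#' @param polarity `"rising"` or `"falling"`.
#' @param min_gradient rejection threshold (grey levels/px).
#' @return List with `row` (sub-pixel 0-based position, `NA` if no edge),
#'   `peak_row` (integer 0-based pre-refinement argmax) and `magnitude`.
#' @export
column_gradient_peak <- function(column, search_range = NULL,
                                 polarity = c("rising", "falling"),
                                 min_gradient = 8) {
  polarity <- match.arg(polarity)
  n <- length(column)
  if (n < 3L) stop("column must have at least 3 samples")
  if (is.null(search_range)) search_range <- 0:(n - 1)
  search_range <- search_range[search_range >= 0 & search_range < n]
  if (length(search_range) == 0L) stop("empty search range")
  m <- matrix(column, ncol = 1)
  g <- central_diff_cols(binomial_smooth_cols(m))[, 1]
  sg <- if (polarity == "rising") g else -g
  cand <- search_range + 1L
  i <- cand[which.max(sg[cand])]
  if (sg[i] < min_gradient)
    return(list(row = NA_real_, peak_row = NA_integer_, magnitude = sg[i]))
  list(row = refine_parabolic(sg, i), peak_row = i - 1L, magnitude = sg[i])
}

# Vectorised per-column signed gradient of one frame: smoothed, central diff.
frame_gradient <- function(frame) central_diff_cols(binomial_smooth_cols(frame))

#' Detect the outer and inner corneal contour of one frame
#'
#' For each column, the outer edge is the first rising gradient peak scanning
#' from the top of the image (local maximum of the smoothed rising gradient
#' exceeding `min_gradient`; ties to the smallest row) and the inner edge is
#' the strongest falling peak within `(outer, outer + max_thickness_px]`.
#' Columns where either edge fails the threshold are flagged invalid.
#'
#' @param frame numeric matrix `[row, col]`, at least 16 x 16.
#' @param config a [contour_config()].
#' @return List with numeric vectors `outer`, `inner` (0-based sub-pixel rows,
#'   `NA` where invalid) and logical `valid_outer`, `valid_inner`.
#' @export
detect_contours <- function(frame, config = contour_config()) {
  h <- nrow(frame); w <- ncol(frame)
  if (h < 16L || w < 16L) stop("frame too small: need at least 16 x 16")
  g <- frame_gradient(frame)
  up <- g[c(1L, seq_len(h - 1L)), , drop = FALSE]
  dn <- g[c(seq_len(h)[-1L], h), , drop = FALSE]
  is_peak <- g > up & g >= dn & g >= config$min_gradient
  is_peak[1L, ] <- g[1L, ] >= dn[1L, ] & g[1L, ] >= config$min_gradient

  outer <- rep(NA_real_, w); inner <- rep(NA_real_, w)
  outer_peak <- rep(NA_integer_, w); inner_peak <- rep(NA_integer_, w)
  for (j in seq_len(w)) {
    i <- which(is_peak[, j])
    if (length(i) == 0L) next
    i <- i[1L]
    outer_peak[j] <- i - 1L  # 0-based, like every exported position
    outer[j] <- refine_parabolic(g[, j], i)
    lo <- i + 1L
    hi <- min(h, i + config$max_thickness_px)
    if (lo <= hi) {
      seg <- -g[lo:hi, j]
      k <- which.max(seg)
      if (seg[k] >= config$min_gradient) {
        inner_peak[j] <- lo + k - 2L  # 0-based
        inner[j] <- refine_parabolic(-g[, j], lo + k - 1L)
      }
    }
  }
  valid_outer <- !is.na(outer)
  valid_inner <- !is.na(inner)
  if (sum(valid_outer) < w / 2)
    stop(sprintf("contour detection failed: %d of %d columns have no outer edge",
                 w - sum(valid_outer), w))
  list(outer = outer, inner = inner,
       valid_outer = valid_outer, valid_inner = valid_inner,
       outer_peak = outer_peak, inner_peak = inner_peak)
}

#' Repair a per-column contour
#'
#' Columns deviating from the running median (window `w_med`) by more than
#' `jump_tol` px are invalidated; invalid runs are filled by linear
#' interpolation between the nearest valid neighbours, and runs touching the
#' edges by nearest-valid extension. The result is finite everywhere.
#'
#' @param raw numeric vector of per-column positions (`NA` where invalid).
#' @param validity logical vector; `FALSE` columns are repaired.
#' @param config a [contour_config()].
#' @return List with `positions` (finite numeric vector) and `validity`
#'   (updated flags; repaired columns are `FALSE`).
#' @export
repair_contour <- function(raw, validity = is.finite(raw),
                           config = contour_config()) {
  x <- raw
  x[!validity] <- NA_real_
  if (sum(is.finite(x)) < 2L) stop("fewer than 2 valid columns; cannot repair")
  filled <- fill_linear(x)
  k <- min(config$w_med, length(x))
  if (k %% 2 == 0L) k <- k - 1L
  med <- if (k >= 3) stats::runmed(filled, k, endrule = "median") else filled
  outlier <- validity & abs(x - med) > config$jump_tol
  validity[outlier] <- FALSE
  x[outlier] <- NA_real_
  if (sum(is.finite(x)) < 2L) stop("fewer than 2 valid columns after outlier removal")
  list(positions = fill_linear(x), validity = validity)
}

#' Detect contours for a whole sequence
#'
#' Applies [detect_contours()] plus [repair_contour()] to every frame. Frames
#' where detection fails entirely (for example an all-dark frame) are
#' tolerated up to `max_failed_frames`: their contours are interpolated in
#' time, per column, from the neighbouring frames and flagged invalid.
#'
#' @param sequence a [frame_sequence()].
#' @param config a [contour_config()].
#' @return A `contour_set`: matrices `outer`, `inner` `[frame, col]` of
#'   0-based sub-pixel rows, logical matrices `valid_outer`, `valid_inner`,
#'   `failed_frames` (0-based indices), and the source geometry.
#' @export
detect_sequence_contours <- function(sequence, config = contour_config()) {
  stopifnot(inherits(sequence, "frame_sequence"))
  n <- sequence$n_frames; w <- sequence$width
  outer <- matrix(NA_real_, n, w); inner <- matrix(NA_real_, n, w)
  vout <- matrix(FALSE, n, w); vinn <- matrix(FALSE, n, w)
  failed <- integer(0)
  for (t in seq_len(n)) {
    det <- tryCatch(detect_contours(sequence$frames[, , t], config),
                    error = function(e) NULL)
    if (is.null(det)) { failed <- c(failed, t); next }
    ro <- tryCatch(repair_contour(det$outer, det$valid_outer, config),
                   error = function(e) NULL)
    if (is.null(ro)) { failed <- c(failed, t); next }
    outer[t, ] <- ro$positions
    vout[t, ] <- ro$validity
    if (sum(det$valid_inner) >= 2L) {
      ri <- repair_contour(det$inner, det$valid_inner, config)
      inner[t, ] <- ri$positions
      vinn[t, ] <- ri$validity
    }
  }
  if (length(failed) > config$max_failed_frames)
    stop(sprintf("contour detection failed on %d frames (max %d): frames %s",
                 length(failed), config$max_failed_frames,
                 paste(failed - 1L, collapse = ", ")))
  if (length(failed) > 0) {
    ok <- setdiff(seq_len(n), failed)
    if (length(ok) < 2L) stop("too few successful frames to interpolate")
    for (j in seq_len(w)) {
      outer[failed, j] <- stats::approx(ok, outer[ok, j], xout = failed,
                                        rule = 2)$y
      if (all(is.finite(inner[ok, j])))
        inner[failed, j] <- stats::approx(ok, inner[ok, j], xout = failed,
                                          rule = 2)$y
    }
  }
  structure(list(outer = outer, inner = inner,
                 valid_outer = vout, valid_inner = vinn,
                 failed_frames = failed - 1L,
                 height = sequence$height, width = w, n_frames = n),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour_set: %d frames x %d columns (%.1f%% outer columns valid)\n",
              x$n_frames, x$width, 100 * mean(x$valid_outer)))
  invisible(x)
}

#' Export contours as a long-format data frame
#'
#' One row per (frame, column) with 0-based indices, sub-pixel edge rows and
#' validity flags; suitable for CSV export.
#'
#' @param x a `contour_set`.
#' @param ... unused.
#' @export
as.data.frame.contour_set <- function(x, ...) {
  n <- x$n_frames; w <- x$width
  data.frame(
    frame = rep(0:(n - 1L), times = w),
    column = rep(0:(w - 1L), each = n),
    outer_row = as.vector(x$outer),
    inner_row = as.vector(x$inner),
    outer_valid = as.vector(x$valid_outer),
    inner_valid = as.vector(x$valid_inner)
  )
}
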