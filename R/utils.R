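# Internal helpers shared across modules.

# Round half away from zero at `decimals` places (the convention used for all
# displayed physical units; R's round() is round-half-even).
round_half_away <- function(x, decimals = 0) {
  s <- 10^decimals
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Last run of decimal digits in a string, as numeric; NA if none.
last_digit_run <- function(x) {
  m <- regmatches(x, gregexpr("[0-9]+", x))
  vapply(m, function(runs) {
    if (length(runs) == 0L) NA_real_ else as.numeric(runs[[length(runs)]])
  }, numeric(1))
}

# Replicate-pad a matrix by `r` rows/cols on each side.
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# 3-tap binomial smoothing of the columns of a matrix (along rows), with
# replicated edges. Used by the contour detector and its tests.
binomial_smooth_cols <- function(m) {
  n <- nrow(m)
  up <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(n)[-1L], n), , drop = FALSE]
  (up + 2 * m + dn) / 4
}

# Central-difference gradient along rows of a matrix (one-sided at the edges).
central_diff_cols <- function(m) {
  n <- nrow(m)
  up <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(n)[-1L], n), , drop = FALSE]
  g <- (dn - up) / 2
  g[1L, ] <- m[2L, ] - m[1L, ]
  g[n, ] <- m[n, ] - m[n - 1L, ]
  g
}

# Fill NAs in a numeric vector by linear interpolation between nearest finite
# neighbours, extending the nearest value at the ends. Errors if < 2 finite.
fill_linear <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2L) stop("need at least 2 valid values to interpolate")
  idx <- seq_along(x)
  stats::approx(idx[ok], x[ok], xout = idx, method = "linear", rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
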