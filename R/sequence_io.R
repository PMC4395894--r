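#' Construct a frame sequence
#'
#' A `frame_sequence` is the in-memory form of a Scheimpflug recording: an
#' ordered stack of grayscale frames with spatial and temporal calibration.
#' Frames are stored as a 3D array indexed `[row, col, frame]` with intensity
#' values in `[0, 255]`; row 0 is the top of the image and rows increase
#' downward (all exported positions are 0-based).
#'
#' @param frames 3D numeric array `[height, width, n_frames]`, values in
#'   `[0, 255]`.
#' @param frame_interval_us microseconds between frames (default 231).
#' @param pixel_pitch_mm millimetres per pixel (default 0.15).
#' @param source_id free-text provenance label used for cache staleness checks.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_interval_us = 231,
                           pixel_pitch_mm = 0.15, source_id = "memory") {
  if (length(dim(frames)) != 3L) stop("frames must be a 3D array [row, col, frame]")
  if (dim(frames)[3] < 2L) stop("sequence too short: need at least 2 frames")
  if (frame_interval_us <= 0 || pixel_pitch_mm <= 0)
    stop("calibration constants must be positive")
  structure(list(
    frames = frames,
    n_frames = dim(frames)[3],
    height = dim(frames)[1],
    width = dim(frames)[2],
    frame_interval_us = frame_interval_us,
    pixel_pitch_mm = pixel_pitch_mm,
    source_id = source_id
  ), class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence: %d frames of %d x %d px, %g us/frame, %g mm/px\n  source: %s\n",
              x$n_frames, x$height, x$width, x$frame_interval_us,
              x$pixel_pitch_mm, x$source_id))
  invisible(x)
}

#' Natural (numeric-aware) ordering of frame file names
#'
#' Tonometer exports are suffix-numbered (`Test1.jpg`, `Test2.jpg`, ...,
#' `Test139.jpg`), so a plain lexicographic sort interleaves them. This orders
#' names by the numeric value of the *last* run of digits in each name.
#' Names containing no digits are flagged with a warning and placed last, in
#' lexicographic order.
#'
#' @param file_names character vector of file names (non-empty).
#' @return The same names, reordered; a permutation of the input.
#' @export
#' @examples
#' normalize_and_sort_paths(c("Test10.jpg", "Test2.jpg", "Test1.jpg"))
normalize_and_sort_paths <- function(file_names) {
  if (length(file_names) == 0L) stop("no input files")
  stems <- tools::file_path_sans_ext(basename(file_names))
  key <- last_digit_run(stems)
  nodigit <- is.na(key)
  if (any(nodigit))
    warning(sprintf("%d file name(s) contain no digits; placed last: %s",
                    sum(nodigit), paste(file_names[nodigit], collapse = ", ")))
  withd <- file_names[!nodigit][order(key[!nodigit], file_names[!nodigit])]
  without <- sort(file_names[nodigit])
  c(withd, without)
}

# Rec. 601 luminance for colour frames read by EBImage (values in [0,1]).
luminance_601 <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) return(img)
  if (d[3] >= 3L)
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  img[, , 1]
}

read_image_frame <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop(sprintf("unreadable file: %s (%s)",
                                                   path, conditionMessage(e))))
  dat <- EBImage::imageData(img)
  dat <- luminance_601(dat)
  # EBImage stores [x = col, y = row]; transpose to [row, col].
  t(dat) * 255
}

#' Load an image sequence from a directory or AVI file
#'
#' Directories of JPEG/PNG/TIFF frames are ordered with
#' [normalize_and_sort_paths()]; AVI containers are read in stream order
#' (uncompressed 8-bit palettized or 24-bit DIB frames). Colour inputs are
#' converted to luminance with Rec. 601 weights.
#'
#' @param path directory of numbered images, or an `.avi` file.
#' @param frame_interval_us,pixel_pitch_mm calibration overrides; defaults
#'   231 us/frame and 0.15 mm/px.
#' @return A [frame_sequence()].
#' @export
load_sequence <- function(path, frame_interval_us = 231, pixel_pitch_mm = 0.15) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(jpe?g|png|tif{1,2})$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) < 2L) stop("sequence too short: fewer than 2 image files")
    files <- normalize_and_sort_paths(files)
    first <- read_image_frame(files[1])
    h <- nrow(first); w <- ncol(first)
    frames <- array(0, dim = c(h, w, length(files)))
    frames[, , 1] <- first
    for (i in seq_along(files)[-1]) {
      f <- read_image_frame(files[i])
      if (nrow(f) != h || ncol(f) != w)
        stop(sprintf("inconsistent frame size in %s: %d x %d, expected %d x %d",
                     basename(files[i]), nrow(f), ncol(f), h, w))
      frames[, , i] <- f
    }
    src <- normalizePath(path)
  } else if (file.exists(path) && grepl("\\.avi$", path, ignore.case = TRUE)) {
    frames <- read_avi_frames(path)
    if (dim(frames)[3] < 2L) stop("sequence too short: fewer than 2 frames in AVI")
    src <- normalizePath(path)
  } else {
    stop(sprintf("input not found or unsupported: %s", path))
  }
  frame_sequence(frames, frame_interval_us, pixel_pitch_mm, source_id = src)
}

#' Per-frame histogram equalization
#'
#' Each frame is independently remapped by its own cumulative intensity
#' distribution onto `[0, 255]` (`out = round(255 * cdf(v))`, half up, on
#' intensities quantized to integer grey levels). The mapping is monotone, so
#' pixel rank order within a frame is preserved; a constant frame maps to a
#' single output level.
#'
#' @param sequence a [frame_sequence()].
#' @return A new `frame_sequence` with equalized frames.
#' @export
equalize_histogram <- function(sequence) {
  stopifnot(inherits(sequence, "frame_sequence"))
  out <- sequence$frames
  n <- sequence$height * sequence$width
  for (t in seq_len(sequence$n_frames)) {
    v <- pmin(pmax(round(out[, , t]), 0), 255)
    counts <- tabulate(v + 1L, nbins = 256L)
    cdf <- cumsum(counts) / n
    out[, , t] <- floor(255 * cdf[v + 1L] + 0.5)
  }
  sequence$frames <- out
  sequence$source_id <- paste0(sequence$source_id, "#equalized")
  sequence
}

# ---- results cache (.cdk: uncompressed tar of meta.json + float64 arrays) ----

CACHE_VERSION <- "corvistk-cache-1"

write_bin_array <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
}

read_bin_array <- function(path, dims) {
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = prod(dims), size = 8, endian = "little")
  array(x, dim = dims)
}

# Flatten an analysis bundle into named numeric arrays for archiving.
bundle_arrays <- function(bundle) {
  cs <- bundle$contours; df <- bundle$field
  arr <- list(
    outer = cs$outer, inner = cs$inner,
    valid_outer = cs$valid_outer + 0, valid_inner = cs$valid_inner + 0,
    baseline = df$baseline, full = df$full, eyeball = df$eyeball,
    cornea = df$cornea, cornea_low = df$cornea_low, vibration = df$vibration
  )
  if (!is.null(bundle$spectrum)) {
    arr$spec_amplitude <- bundle$spectrum$amplitude
    arr$spec_freqs <- bundle$spectrum$freqs
  }
  arr
}

#' Save or load an analysis bundle cache
#'
#' Once a sequence has been analysed, the contours, deformation components,
#' spectrum and report are archived next to the input (extension `.cdk`) so
#' re-analysis needs no recomputation. The archive is an uncompressed tar
#' holding a JSON metadata block (version, source id, calibration, array
#' shapes) plus each numeric array as little-endian float64. A cache whose
#' source id or calibration does not match the requested analysis is rejected
#' with a warning and recomputation proceeds.
#'
#' @param bundle a `corvis_analysis` list (contours, field, spectrum, report).
#' @param path file path for the `.cdk` archive.
#' @return `save_results()`: `path`, invisibly. `load_results()`: the restored
#'   bundle, or `NULL` if the cache is absent or stale.
#' @export
save_results <- function(bundle, path) {
  stopifnot(!is.null(bundle$contours), !is.null(bundle$field))
  arrays <- bundle_arrays(bundle)
  tmp <- tempfile("cdk")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  meta <- list(
    version = CACHE_VERSION,
    source_id = bundle$source_id %||% "unknown",
    frame_interval_us = bundle$field$frame_interval_us,
    pixel_pitch_mm = bundle$field$pixel_pitch_mm,
    baseline_frames = bundle$field$baseline_frames,
    scleral_margin = bundle$field$scleral_margin,
    cutoff_hz = bundle$field$cutoff_hz,
    arrays = lapply(arrays, function(a) as.integer(if (is.null(dim(a))) length(a) else dim(a))),
    report = if (is.null(bundle$report)) NULL else unclass(bundle$report)
  )
  jsonlite::write_json(meta, file.path(tmp, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  for (nm in names(arrays))
    write_bin_array(arrays[[nm]], file.path(tmp, paste0(nm, ".bin")))
  owd <- setwd(tmp)
  utils::tar(file.path(owd, "cache.tar.tmp"), files = ".", tar = "internal")
  setwd(owd)
  file.rename("cache.tar.tmp", path)
  invisible(path)
}

#' @rdname save_results
#' @param source_id,frame_interval_us,pixel_pitch_mm expected provenance and
#'   calibration; mismatches invalidate the cache.
#' @export
load_results <- function(path, source_id = NULL, frame_interval_us = NULL,
                         pixel_pitch_mm = NULL) {
  if (!file.exists(path)) {
    message(sprintf("no cache at %s", path))
    return(NULL)
  }
  tmp <- tempfile("cdk")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::untar(path, exdir = tmp, tar = "internal")
  meta <- jsonlite::read_json(file.path(tmp, "meta.json"), simplifyVector = TRUE)
  stale <- !identical(meta$version, CACHE_VERSION) ||
    (!is.null(source_id) && !identical(meta$source_id, source_id)) ||
    (!is.null(frame_interval_us) && meta$frame_interval_us != frame_interval_us) ||
    (!is.null(pixel_pitch_mm) && meta$pixel_pitch_mm != pixel_pitch_mm)
  if (stale) {
    warning("cache is stale (version/source/calibration mismatch); ignoring it")
    return(NULL)
  }
  arrays <- lapply(names(meta$arrays), function(nm) {
    read_bin_array(file.path(tmp, paste0(nm, ".bin")), unlist(meta$arrays[[nm]]))
  })
  names(arrays) <- names(meta$arrays)
  drop1 <- function(a) if (length(dim(a)) == 1L) as.numeric(a) else a
  contours <- structure(list(
    outer = arrays$outer, inner = arrays$inner,
    valid_outer = arrays$valid_outer > 0, valid_inner = arrays$valid_inner > 0,
    n_frames = nrow(arrays$outer), width = ncol(arrays$outer),
    height = NA_integer_
  ), class = "contour_set")
  field <- structure(list(
    baseline = drop1(arrays$baseline), full = arrays$full,
    eyeball = arrays$eyeball, cornea = arrays$cornea,
    cornea_low = arrays$cornea_low, vibration = arrays$vibration,
    frame_interval_us = meta$frame_interval_us,
    pixel_pitch_mm = meta$pixel_pitch_mm,
    baseline_frames = meta$baseline_frames,
    scleral_margin = meta$scleral_margin,
    cutoff_hz = meta$cutoff_hz
  ), class = "deformation_field")
  spectrum <- NULL
  if (!is.null(arrays$spec_amplitude)) {
    spectrum <- structure(list(
      amplitude = arrays$spec_amplitude, freqs = drop1(arrays$spec_freqs),
      n_frames = nrow(arrays$full),
      sampling_rate_hz = 1e6 / meta$frame_interval_us
    ), class = "spectral_map")
  }
  report <- meta$report
  if (!is.null(report)) class(report) <- "biomech_report"
  list(contours = contours, field = field, spectrum = spectrum,
       report = report, source_id = meta$source_id)
}
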