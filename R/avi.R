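# Minimal RIFF/AVI support for uncompressed DIB video, the container variant
# the tonometer exports reduce to. Writes 8-bit palettized (grayscale ramp)
# frames; reads 8-bit palettized and 24-bit BI_RGB streams. No installed R
# package handles AVI, so the two dozen RIFF chunks involved are parsed here
# directly.

fourcc <- function(x) charToRaw(x)

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

riff_chunk <- function(id, payload) {
  if (length(payload) %% 2L == 1L) payload <- c(payload, as.raw(0))
  c(fourcc(id), u32(length(payload)), payload)
}

riff_list <- function(type, payload) riff_chunk("LIST", c(fourcc(type), payload))

#' Write frames as an uncompressed 8-bit AVI
#'
#' Frames are stored as palettized DIB (grayscale ramp palette), one key frame
#' per chunk, with a standard idx1 index. The stream header records
#' `frame_interval_us` as the scale over a 1 MHz rate.
#'
#' @param frames 3D array `[row, col, frame]`, values in `[0, 255]`.
#' @param path output `.avi` path.
#' @param frame_interval_us microseconds per frame, stored in the stream header.
#' @return `path`, invisibly.
#' @export
write_avi_frames <- function(frames, path, frame_interval_us = 231) {
  d <- dim(frames)
  h <- d[1]; w <- d[2]; n <- d[3]
  stride <- ceiling(w / 4) * 4
  frame_bytes <- stride * h

  avih <- c(u32(frame_interval_us), u32(frame_bytes * 1e6 / frame_interval_us),
            u32(0), u32(0x10), u32(n), u32(0), u32(1), u32(frame_bytes),
            u32(w), u32(h), u32(0), u32(0), u32(0), u32(0))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32(0), u16(0), u16(0), u32(0),
            u32(frame_interval_us), u32(1e6), u32(0), u32(n), u32(frame_bytes),
            u32(0xFFFFFFFF - 4294967296), u32(0),
            u16(0), u16(0), u16(w), u16(h))
  palette <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))
  strf <- c(u32(40), u32(w), u32(h), u16(1), u16(8), u32(0), u32(frame_bytes),
            u32(0), u32(0), u32(256), u32(0), palette)
  hdrl <- riff_list("hdrl", c(riff_chunk("avih", avih),
                              riff_list("strl", c(riff_chunk("strh", strh),
                                                  riff_chunk("strf", strf)))))

  q <- pmin(pmax(round(frames), 0), 255)
  movi_payload <- raw(0)
  offsets <- integer(n)
  pos <- 4L  # after the 'movi' fourcc
  chunks <- vector("list", n)
  for (t in seq_len(n)) {
    # DIB rows are bottom-up; pad each row to the 4-byte stride.
    m <- q[h:1, , t, drop = TRUE]
    rowdat <- matrix(as.raw(0), nrow = stride, ncol = h)
    rowdat[seq_len(w), ] <- as.raw(t(m))
    chunks[[t]] <- riff_chunk("00db", as.vector(rowdat))
    offsets[t] <- pos
    pos <- pos + length(chunks[[t]])
  }
  movi <- riff_list("movi", do.call(c, chunks))
  idx <- do.call(c, lapply(seq_len(n), function(t)
    c(fourcc("00db"), u32(0x10), u32(offsets[t]), u32(frame_bytes))))
  idx1 <- riff_chunk("idx1", idx)

  body <- c(fourcc("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32(length(body)), body), con)
  invisible(path)
}

read_u32 <- function(raw, off) {
  sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

read_u16 <- function(raw, off) sum(as.integer(raw[off + 1:2]) * c(1, 256))

# Walk RIFF chunks in raw[from..to]; returns list of (id, type, start, size).
riff_walk <- function(dat, from, to) {
  out <- list()
  off <- from
  while (off + 8 <= to) {
    id <- rawToChar(dat[(off + 1):(off + 4)])
    size <- read_u32(dat, off + 4)
    type <- if (id %in% c("RIFF", "LIST") && off + 12 <= to)
      rawToChar(dat[(off + 9):(off + 12)]) else ""
    out[[length(out) + 1L]] <- list(id = id, type = type,
                                    start = off + 8, size = size)
    off <- off + 8 + size + (size %% 2)
  }
  out
}

#' Read an uncompressed AVI into a frame array
#'
#' Supports BI_RGB streams with 8-bit palettized or 24-bit BGR frames.
#' Palettized frames are mapped through the palette's Rec. 601 luminance;
#' 24-bit frames are converted the same way.
#'
#' @param path `.avi` file.
#' @return 3D array `[row, col, frame]`, values in `[0, 255]`.
#' @export
read_avi_frames <- function(path) {
  dat <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(dat[1:4]) != "RIFF" || rawToChar(dat[9:12]) != "AVI ")
    stop(sprintf("not an AVI file: %s", path))
  top <- riff_walk(dat, 12, length(dat))
  hdrl <- Filter(function(x) x$id == "LIST" && x$type == "hdrl", top)
  movi <- Filter(function(x) x$id == "LIST" && x$type == "movi", top)
  if (length(hdrl) == 0 || length(movi) == 0) stop("malformed AVI: missing hdrl/movi")
  inner <- riff_walk(dat, hdrl[[1]]$start + 4, hdrl[[1]]$start + hdrl[[1]]$size)
  strl <- Filter(function(x) x$id == "LIST" && x$type == "strl", inner)
  if (length(strl) == 0) stop("malformed AVI: no stream list")
  sl <- riff_walk(dat, strl[[1]]$start + 4, strl[[1]]$start + strl[[1]]$size)
  strf <- Filter(function(x) x$id == "strf", sl)
  if (length(strf) == 0) stop("malformed AVI: no stream format")
  fo <- strf[[1]]$start
  w <- read_u32(dat, fo + 4)
  h <- read_u32(dat, fo + 8)
  bits <- read_u16(dat, fo + 14)
  compression <- read_u32(dat, fo + 16)
  if (compression != 0)
    stop("unsupported AVI codec: only uncompressed (BI_RGB) streams are read")
  pal_lum <- NULL
  if (bits == 8) {
    ncol_pal <- read_u32(dat, fo + 32)
    if (ncol_pal == 0) ncol_pal <- 256
    pal <- matrix(as.integer(dat[(fo + 40 + 1):(fo + 40 + 4 * ncol_pal)]),
                  nrow = 4)
    pal_lum <- 0.114 * pal[1, ] + 0.587 * pal[2, ] + 0.299 * pal[3, ]  # BGR0
  } else if (bits != 24) {
    stop(sprintf("unsupported AVI bit depth: %d", bits))
  }
  frames_raw <- Filter(function(x) x$id %in% c("00db", "00dc"),
                       riff_walk(dat, movi[[1]]$start + 4,
                                 movi[[1]]$start + movi[[1]]$size))
  if (length(frames_raw) == 0) stop("AVI contains no frames")
  out <- array(0, dim = c(h, w, length(frames_raw)))
  bpp <- if (bits == 8) 1L else 3L
  stride <- ceiling(w * bpp / 4) * 4
  for (t in seq_along(frames_raw)) {
    fr <- frames_raw[[t]]
    bytes <- dat[(fr$start + 1):(fr$start + fr$size)]
    m <- matrix(as.integer(bytes[seq_len(stride * h)]), nrow = stride)
    if (bits == 8) {
      img <- matrix(pal_lum[m[seq_len(w), ] + 1L], nrow = w)
    } else {
      b <- m[seq(1, by = 3, length.out = w), ]
      g <- m[seq(2, by = 3, length.out = w), ]
      r <- m[seq(3, by = 3, length.out = w), ]
      img <- 0.299 * r + 0.587 * g + 0.114 * b
    }
    out[, , t] <- t(img)[h:1, ]  # bottom-up DIB -> top-down rows
  }
  out
}
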