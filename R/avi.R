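# Minimal RIFF/AVI container I/O for uncompressed (BI_RGB, 24-bit DIB)
# video.  Covers the round trip needed for a self-contained pipeline:
# the synthetic renderer writes AVI, the analysis loads it.  Compressed
# codecs (and the MP4 container) need a codec library and are not
# handled here.

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
fourcc <- function(s) charToRaw(s)

riff_chunk <- function(id, payload) {
  stopifnot(nchar(id) == 4L)
  pad <- if (length(payload) %% 2L == 1L) as.raw(0) else raw(0)
  c(fourcc(id), u32(length(payload)), payload, pad)
}

riff_list <- function(type, payload) {
  riff_chunk("LIST", c(fourcc(type), payload))
}

# One frame as a bottom-up, 4-byte-row-aligned, BGR DIB bitmap.
frame_to_dib <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  g <- as.integer(round(pmin(pmax(frame, 0), 1) * 255))
  dim(g) <- c(h, w)
  stride <- w * 3L
  padlen <- (4L - stride %% 4L) %% 4L
  rows <- vector("list", h)
  padding <- as.raw(rep(0L, padlen))
  for (r in seq_len(h)) {
    row <- g[h - r + 1L, ]                   # bottom-up row order
    rows[[r]] <- c(as.raw(rep(row, each = 3L)), padding)
  }
  do.call(c, rows)
}

dib_to_frame <- function(bytes, w, h) {
  stride <- w * 3L
  padlen <- (4L - stride %% 4L) %% 4L
  full <- stride + padlen
  if (length(bytes) < full * h) {
    stop("AVI frame chunk too short for declared dimensions", call. = FALSE)
  }
  m <- matrix(as.integer(bytes[seq_len(full * h)]), nrow = full)  # one col per row
  bgr <- m[seq_len(stride), , drop = FALSE]
  b <- bgr[seq(1L, stride, by = 3L), , drop = FALSE]
  g <- bgr[seq(2L, stride, by = 3L), , drop = FALSE]
  r <- bgr[seq(3L, stride, by = 3L), , drop = FALSE]
  # standard luma weighting for color content; identity for gray
  lum <- (0.299 * r + 0.587 * g + 0.114 * b) / 255
  t(lum)[h:1, , drop = FALSE]                 # back to top-down rows
}

#' Write a frame sequence as an uncompressed AVI file
#'
#' Encodes every frame as an uncompressed 24-bit DIB ("full frames")
#' inside a standard RIFF/AVI container; any mainstream video player or
#' reader can open the result.  The frame rate is stored exactly as a
#' rational (`fps * 1000 / 1000`).
#'
#' @param seq A [frame_sequence()].
#' @param path Output file path (conventionally `.avi`).
#' @export
write_video_avi <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  h <- seq$height; w <- seq$width
  n <- dim(seq$frames)[3]
  stride <- w * 3L + (4L - (w * 3L) %% 4L) %% 4L
  frame_bytes <- stride * h
  avih <- c(u32(round(1e6 / seq$fps)), u32(frame_bytes * seq$fps),
            u32(0), u32(0x10),                 # AVIF_HASINDEX
            u32(n), u32(0), u32(1), u32(frame_bytes),
            u32(w), u32(h), u32(0), u32(0), u32(0), u32(0))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32(0), u16(0), u16(0),
            u32(0), u32(1000), u32(round(seq$fps * 1000)),
            u32(0), u32(n), u32(frame_bytes), u32(-1), u32(0),
            u16(0), u16(0), u16(w), u16(h))
  strf <- c(u32(40), u32(w), u32(h), u16(1), u16(24), u32(0),
            u32(frame_bytes), u32(0), u32(0), u32(0), u32(0))
  hdrl <- riff_list("hdrl", c(riff_chunk("avih", avih),
                              riff_list("strl", c(riff_chunk("strh", strh),
                                                  riff_chunk("strf", strf)))))
  movi_payload <- fourcc("movi")
  idx <- raw(0)
  offset <- 4L                                 # offset of first chunk fourcc
  for (i in seq_len(n)) {
    dib <- frame_to_dib(seq$frames[, , i])
    movi_payload <- c(movi_payload, riff_chunk("00db", dib))
    idx <- c(idx, fourcc("00db"), u32(0x10), u32(offset), u32(length(dib)))
    offset <- offset + 8L + length(dib) + (length(dib) %% 2L)
  }
  movi <- riff_chunk("LIST", movi_payload)
  body <- c(fourcc("AVI "), hdrl, movi, riff_chunk("idx1", idx))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(fourcc("RIFF"), con)
  writeBin(u32(length(body)), con)
  writeBin(body, con)
  invisible(path)
}

read_u32 <- function(bytes, at) {
  sum(as.numeric(bytes[at:(at + 3L)]) * c(1, 256, 65536, 16777216))
}
read_u16 <- function(bytes, at) {
  sum(as.numeric(bytes[at:(at + 1L)]) * c(1, 256))
}
read_fourcc <- function(bytes, at) {
  four <- bytes[at:(at + 3L)]
  if (any(four == as.raw(0))) return("")     # not a printable chunk id
  rawToChar(four)
}

# Flat walk over all chunks; returns list of (id, listtype, start, size).
# Tolerates truncated files: declared extents are capped at the buffer.
walk_riff <- function(bytes, from, to, acc = list()) {
  at <- from
  to <- min(to, length(bytes))
  while (at + 7L <= to) {
    id <- read_fourcc(bytes, at)
    size <- read_u32(bytes, at + 4L)
    start <- at + 8L
    if (start + size - 1L > length(bytes)) {
      size <- max(0, length(bytes) - start + 1L)   # truncated final chunk
    }
    if (id == "LIST" && size >= 4L) {
      type <- read_fourcc(bytes, start)
      acc[[length(acc) + 1L]] <- list(id = id, type = type,
                                      start = start + 4L, size = size - 4L)
      acc <- walk_riff(bytes, start + 4L, start + size - 1L, acc)
    } else {
      acc[[length(acc) + 1L]] <- list(id = id, type = NA_character_,
                                      start = start, size = size)
    }
    at <- start + size + (size %% 2L)
  }
  acc
}

#' Load a video file as a grayscale frame sequence
#'
#' Reads an AVI container holding uncompressed 24-bit DIB frames (as
#' written by [write_video_avi()] or by common tools with the
#' "rawvideo"/"full frames" codec).  Frames are converted to grayscale
#' intensity on \[0,1\] by standard luma weighting; the frame rate is
#' taken from the stream header (exact rational), falling back to the
#' main header's frame period, falling back to an explicit `fps`
#' argument.
#'
#' MP4 files and codec-compressed AVI streams cannot be decoded without
#' a codec library: re-encode to uncompressed AVI first (e.g.
#' `ffmpeg -i in.mp4 -vcodec rawvideo -pix_fmt bgr24 out.avi`).
#'
#' @param path Path to an AVI file.
#' @param fps Optional frame-rate override, required only when the
#'   container lacks rate metadata.
#' @return A [frame_sequence()].
#' @export
load_video <- function(path, fps = NULL) {
  if (!file.exists(path)) stop(sprintf("video file not found: %s", path), call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 24) stop(sprintf("not a readable AVI file: %s", path), call. = FALSE)
  bytes <- readBin(path, "raw", n = sz)
  magic <- read_fourcc(bytes, 1L)
  if (magic != "RIFF") {
    hint <- if (grepl("\\.mp4$", path, ignore.case = TRUE) ||
                (sz > 11 && read_fourcc(bytes, 5L) == "ftyp")) {
      " (this looks like an MP4; decoding it requires a codec library -- re-encode to uncompressed AVI first)"
    } else ""
    stop(sprintf("%s is not a RIFF/AVI file%s", path, hint), call. = FALSE)
  }
  if (read_fourcc(bytes, 9L) != "AVI ") {
    stop(sprintf("%s is RIFF but not an AVI container", path), call. = FALSE)
  }
  chunks <- walk_riff(bytes, 13L, min(sz, 8 + read_u32(bytes, 5L)))
  ids <- vapply(chunks, `[[`, "", "id")
  w <- h <- NULL; bitcount <- NULL; compression <- NULL
  file_fps <- NULL
  for (ch in chunks) {
    if (ch$id == "strh" && read_fourcc(bytes, ch$start) == "vids") {
      scale <- read_u32(bytes, ch$start + 20L)
      rate <- read_u32(bytes, ch$start + 24L)
      if (scale > 0 && rate > 0) file_fps <- rate / scale
    } else if (ch$id == "strf" && is.null(w)) {
      w <- read_u32(bytes, ch$start + 4L)
      h <- read_u32(bytes, ch$start + 8L)
      bitcount <- read_u16(bytes, ch$start + 14L)
      compression <- read_u32(bytes, ch$start + 16L)
    } else if (ch$id == "avih" && is.null(file_fps)) {
      usec <- read_u32(bytes, ch$start)
      if (usec > 0) file_fps <- 1e6 / usec
    }
  }
  if (is.null(w)) stop(sprintf("%s: no video stream format header found", path), call. = FALSE)
  if (!is.null(compression) && compression != 0) {
    stop(sprintf("%s: compressed AVI stream (codec fourcc/id %s) is not supported; re-encode to uncompressed frames", path, compression), call. = FALSE)
  }
  if (is.null(bitcount) || bitcount != 24) {
    stop(sprintf("%s: only 24-bit uncompressed frames are supported (got %s-bit)",
                 path, bitcount), call. = FALSE)
  }
  if (is.null(fps)) {
    fps <- file_fps
    if (is.null(fps)) {
      stop(sprintf("%s has no frame-rate metadata; pass fps explicitly", path),
           call. = FALSE)
    }
  }
  frame_idx <- which(ids %in% c("00db", "00dc"))
  if (length(frame_idx) < 2L) {
    stop(sprintf("%s: found %d frame(s); at least 2 are required for frame differencing",
                 path, length(frame_idx)), call. = FALSE)
  }
  frames <- array(0, dim = c(h, w, length(frame_idx)))
  for (k in seq_along(frame_idx)) {
    ch <- chunks[[frame_idx[k]]]
    frames[, , k] <- dib_to_frame(bytes[ch$start:(ch$start + ch$size - 1L)], w, h)
  }
  message(sprintf("loaded %s: %d frames of %dx%d px at %g fps",
                  basename(path), length(frame_idx), w, h, fps))
  frame_sequence(frames, fps)
}
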