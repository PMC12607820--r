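#' Ordered grayscale frame sequence
#'
#' Frames are stored as a `height x width x n` numeric array with
#' intensities on \[0,1\], row index increasing downward and column
#' index increasing rightward (0-based pixel coordinates in all
#' reported positions: x = column = mediolateral, y = row).
#'
#' @param frames A 3-D array `height x width x n`, n >= 2, values in
#'   \[0,1\], or a list of equal-sized matrices.
#' @param fps Frames per second (> 0).
#' @return An object of class `frame_sequence` with fields `frames`,
#'   `fps`, `width`, `height`.
#' @export
frame_sequence <- function(frames, fps) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop_param("frames", "all frames must share dimensions")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_param("frames", "must be a height x width x n array")
  }
  if (dim(frames)[3] < 2L) {
    stop("frame sequence needs at least 2 frames", call. = FALSE)
  }
  if (min(frames) < 0 || max(frames) > 1) {
    stop_param("frames", "intensities must lie in [0,1]")
  }
  check_scalar_num(fps, "fps", lower = 0, strict_lower = TRUE)
  structure(list(frames = frames, fps = fps,
                 width = dim(frames)[2], height = dim(frames)[1]),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames of %dx%d px @ %g fps\n",
              dim(x$frames)[3], x$width, x$height, x$fps))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) dim(x$frames)[3]

#' Rectangular region of interest
#'
#' 0-based, half-open pixel bounds: columns `[left, right)`, rows
#' `[top, bottom)`.  The ROI is drawn over the subject's trunk so that
#' background clutter is excluded before motion detection.
#'
#' @param left,top,right,bottom Pixel indices with
#'   `0 <= left < right` and `0 <= top < bottom`.
#' @export
region_of_interest <- function(left, top, right, bottom) {
  for (v in list(left = left, top = top, right = right, bottom = bottom)) {
    if (v != round(v)) stop_param("roi", "bounds must be integers")
  }
  if (!(left >= 0 && left < right)) stop_param("left/right", "need 0 <= left < right")
  if (!(top >= 0 && top < bottom)) stop_param("top/bottom", "need 0 <= top < bottom")
  structure(list(left = as.integer(left), top = as.integer(top),
                 right = as.integer(right), bottom = as.integer(bottom)),
            class = "region_of_interest")
}

#' Motion-detection configuration
#'
#' @param threshold Absolute intensity-difference cutoff on (0,1);
#'   pixels with `|curr - prev| > threshold` are classified moving.
#'   Default 0.15.  A difference exactly equal to the threshold counts
#'   as static (deterministic tie rule; the event has measure zero on
#'   real data).
#' @param morph_open_radius,morph_close_radius Disc radii in pixels of
#'   the morphological opening and closing applied to the raw mask
#'   (defaults 0 and 2): opening removes speckle no larger than the
#'   disc, closing fills comparable gaps.  Opening is off by default
#'   because sub-pixel inter-frame motion produces changed bands only
#'   1-2 px thick, which any opening erases wholesale; isolated-pixel
#'   noise is already removed by the component-area filter.
#' @param min_component_area Connected components (8-connectivity)
#'   smaller than this many pixels are removed (default 20).
#' @param empty_mask_policy What to do when a denoised mask has no
#'   moving pixel: `"carry_forward"` repeats the last valid centroid
#'   (leading empties are back-filled from the first valid one);
#'   `"mark_missing"` records a gap and fills it by linear
#'   interpolation.
#' @export
motion_config <- function(threshold = 0.15, morph_open_radius = 0,
                          morph_close_radius = 2, min_component_area = 20,
                          empty_mask_policy = c("carry_forward", "mark_missing")) {
  empty_mask_policy <- match.arg(empty_mask_policy)
  check_scalar_num(threshold, "threshold", lower = 0, upper = 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_num(morph_open_radius, "morph_open_radius", lower = 0)
  check_scalar_num(morph_close_radius, "morph_close_radius", lower = 0)
  check_scalar_num(min_component_area, "min_component_area", lower = 0)
  structure(list(threshold = threshold,
                 morph_open_radius = as.integer(morph_open_radius),
                 morph_close_radius = as.integer(morph_close_radius),
                 min_component_area = as.integer(min_component_area),
                 empty_mask_policy = empty_mask_policy),
            class = "motion_config")
}

#' Crop and normalize a frame sequence
#'
#' Crops every frame to the ROI and min-max normalizes each frame
#' independently to \[0,1\], which neutralizes global brightness
#' fluctuation (flicker, auto-exposure drift) between frames.  A
#' constant frame maps to all zeros rather than dividing by zero.
#'
#' @param seq A [frame_sequence()].
#' @param roi A [region_of_interest()], or `NULL` for the full frame.
#' @return A [frame_sequence()] of the ROI dimensions.
#' @export
preprocess <- function(seq, roi = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  fr <- seq$frames
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "region_of_interest"))
    if (roi$right > seq$width || roi$bottom > seq$height) {
      stop_param("roi", sprintf("exceeds frame dimensions %dx%d",
                                seq$width, seq$height))
    }
    fr <- fr[(roi$top + 1L):roi$bottom, (roi$left + 1L):roi$right, , drop = FALSE]
  }
  n <- dim(fr)[3]
  for (i in seq_len(n)) {
    f <- fr[, , i]
    lo <- min(f); hi <- max(f)
    fr[, , i] <- if (hi > lo) (f - lo) / (hi - lo) else 0
  }
  frame_sequence(fr, seq$fps)
}

#' Binary motion mask from two consecutive frames
#'
#' `mask[p] = 1` iff the absolute intensity difference at pixel p
#' exceeds the threshold, else 0.
#'
#' @param prev,curr Matrices of equal dimensions with values on \[0,1\].
#' @param cfg A [motion_config()].
#' @return A 0/1 integer matrix of the frame dimensions.
#' @export
frame_difference_mask <- function(prev, curr, cfg = motion_config()) {
  if (!identical(dim(prev), dim(curr))) {
    stop("frames have mismatched dimensions", call. = FALSE)
  }
  mask <- abs(curr - prev) > cfg$threshold
  storage.mode(mask) <- "integer"
  mask
}

# 8-connectivity component areas.  EBImage::bwlabel is 4-connected, so
# labels that touch diagonally are merged with a union-find pass over
# the (small) label set; returns the per-pixel merged label matrix.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right diagonal pairs
  c_ <- lab[-1, -nc]; d <- lab[-nr, -1]   # up-right diagonal pairs
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  lab
}

#' Morphological denoising of a motion mask
#'
#' Applies opening (disc of radius `morph_open_radius`), then closing
#' (disc of radius `morph_close_radius`), then removes 8-connected
#' components smaller than `min_component_area` pixels.  Isolated pixel
#' errors and small spurious regions are eliminated while the
#' trunk-scale silhouette is preserved.
#'
#' @param mask A 0/1 matrix (see [frame_difference_mask()]).
#' @param cfg A [motion_config()].
#' @return A 0/1 integer matrix.
#' @export
denoise_mask <- function(mask, cfg = motion_config()) {
  m <- mask
  storage.mode(m) <- "double"
  if (cfg$morph_open_radius > 0 && any(m > 0)) {
    m <- EBImage::opening(m, disc_brush(cfg$morph_open_radius))
  }
  if (cfg$morph_close_radius > 0 && any(m > 0)) {
    m <- EBImage::closing(m, disc_brush(cfg$morph_close_radius))
  }
  m <- matrix(as.integer(m > 0.5), nrow(mask), ncol(mask))
  if (cfg$min_component_area > 0 && any(m > 0)) {
    lab <- label_components_8(m)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= cfg$min_component_area)
    m <- matrix(as.integer(lab %in% keep & lab > 0), nrow(mask), ncol(mask))
  }
  m
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * radius + 1L, shape = "disc")
}

# Centroid of a binary mask in 0-based (x = col, y = row) coordinates;
# NULL if empty.
mask_centroid <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

#' Extract the silhouette-centroid (COM) trajectory from video
#'
#' Runs the full image-processing chain: crop + per-frame normalization
#' ([preprocess()]), frame differencing at the configured threshold,
#' morphological denoising, and per-pair centroid extraction (mean row
#' and column of the moving pixels).  The centroid of the difference of
#' frames (i-1, i) is timestamped at frame i, so N frames yield N-1
#' trajectory samples at the sequence frame rate, in pixel units and
#' ROI-local 0-based coordinates.
#'
#' Empty masks (no moving pixel) are handled per
#' `cfg$empty_mask_policy`; if every mask is empty the subject is
#' either perfectly still or the threshold is too high for the scene
#' contrast, and an error says so.
#'
#' @param seq A [frame_sequence()].
#' @param roi A [region_of_interest()] or `NULL` for the full frame.
#' @param cfg A [motion_config()].
#' @return A pixel-unit [trajectory()] of N-1 samples with attributes
#'   `mask_area_px` (moving-pixel count per sample) and `n_empty`
#'   (number of empty masks encountered).
#' @export
extract_com_trajectory <- function(seq, roi = NULL, cfg = motion_config()) {
  pp <- preprocess(seq, roi)
  fr <- pp$frames
  n <- dim(fr)[3]
  h <- dim(fr)[1]; w <- dim(fr)[2]
  # raw masks for all consecutive pairs at once
  d <- abs(fr[, , 2:n, drop = FALSE] - fr[, , 1:(n - 1), drop = FALSE])
  masks <- array(as.numeric(d > cfg$threshold), dim = dim(d))
  # morphology on the whole stack (EBImage applies brushes per frame)
  if (cfg$morph_open_radius > 0) {
    masks <- EBImage::opening(masks, disc_brush(cfg$morph_open_radius))
  }
  if (cfg$morph_close_radius > 0) {
    masks <- EBImage::closing(masks, disc_brush(cfg$morph_close_radius))
  }
  xs <- rep(NA_real_, n - 1)
  ys <- rep(NA_real_, n - 1)
  area <- integer(n - 1)
  for (i in seq_len(n - 1)) {
    m <- matrix(as.integer(masks[, , i] > 0.5), h, w)
    if (cfg$min_component_area > 0 && any(m > 0)) {
      lab <- label_components_8(m)
      areas <- tabulate(lab[lab > 0])
      keep <- which(areas >= cfg$min_component_area)
      m <- matrix(as.integer(lab %in% keep & lab > 0), h, w)
    }
    cen <- mask_centroid(m)
    if (!is.null(cen)) {
      xs[i] <- cen["x"]; ys[i] <- cen["y"]; area[i] <- sum(m)
    }
  }
  n_empty <- sum(is.na(xs))
  if (n_empty == n - 1) {
    stop("no motion detected in any frame pair: the subject may be perfectly ",
         "still, or the threshold is too high for the scene contrast ",
         "(consider lowering `threshold` or adding surface texture)",
         call. = FALSE)
  }
  if (n_empty > 0) {
    if (cfg$empty_mask_policy == "carry_forward") {
      first_valid <- which(!is.na(xs))[1]
      if (first_valid > 1) {  # back-fill leading empties
        xs[1:(first_valid - 1)] <- xs[first_valid]
        ys[1:(first_valid - 1)] <- ys[first_valid]
      }
      for (i in seq_len(n - 1)[-1]) {
        if (is.na(xs[i])) { xs[i] <- xs[i - 1]; ys[i] <- ys[i - 1] }
      }
    } else {  # mark_missing: linear interpolation across gaps
      idx <- seq_len(n - 1)
      ok <- !is.na(xs)
      xs <- approx(idx[ok], xs[ok], xout = idx, rule = 2)$y
      ys <- approx(idx[ok], ys[ok], xout = idx, rule = 2)$y
    }
  }
  out <- trajectory(xs, ys, pp$fps, units = "pixel")
  attr(out, "mask_area_px") <- area
  attr(out, "n_empty") <- n_empty
  out
}
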