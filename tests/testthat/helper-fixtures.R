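# Shared fixtures built in code at test time.

# A random smooth trajectory (no package generator involved) for
# algebraic property checks.
random_trajectory <- function(n = 50, rate = 30, units = "pixel") {
  trajectory(cumsum(rnorm(n)), cumsum(rnorm(n)), rate, units = units)
}

# A deterministic textured test video: silhouette moving with the given
# per-frame centre offsets (n = length(offsets_x) frames).
moving_blob_video <- function(offsets_x, offsets_y = rep(0, length(offsets_x)),
                              width = 680, height = 48, half_w = 10, half_h = 14,
                              texture = 0.45, fps = 30) {
  rp <- render_params(frame_width = width, frame_height = height,
                      silhouette_half_width = half_w,
                      silhouette_half_height = half_h,
                      texture_contrast = texture,
                      foreground_level = if (texture > 0.5) 0.5 else 0.45,
                      fps = fps)
  render_silhouette_video(trajectory(offsets_x, offsets_y, fps), rp)
}

# Brute-force reference mask: plain thresholded absolute difference,
# computed without any package helper.
reference_diff_mask <- function(prev, curr, threshold = 0.15) {
  matrix(as.integer(abs(curr - prev) > threshold), nrow(prev), ncol(prev))
}

# Brute-force centroid (0-based x = col, y = row).
reference_centroid <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}
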