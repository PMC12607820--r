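#' Parameters of the band-limited stochastic sway model
#'
#' The generator models quiet-stance sway per axis as band-limited
#' Gaussian noise: white noise low-pass filtered to `bandwidth_hz` and
#' rescaled so the sample SD equals the requested amplitude.  This is
#' the simplest stationary model with independently controllable
#' amplitude and bandwidth; it makes no biomechanical claim, but it is
#' the natural counterpart of summary metrics (velocities and path
#' lengths) that are themselves stationary descriptors.
#'
#' @param amplitude_x,amplitude_y RMS sway amplitude per axis, in the
#'   trajectory's units (pixels as generated); must be >= 0.
#' @param bandwidth_hz Upper frequency bound of sway power in Hz;
#'   0 < bandwidth_hz < rate_hz/2.
#' @param duration_s Trial length in seconds (default 30, the standard
#'   quiet-stance trial length).
#' @param rate_hz Sampling rate of the generated trajectory (default 30,
#'   a typical smartphone video frame rate).
#' @param seed Integer RNG seed.
#' @export
sway_model_params <- function(amplitude_x = 2, amplitude_y = 3,
                              bandwidth_hz = 2, duration_s = 30,
                              rate_hz = 30, seed = 1L) {
  check_scalar_num(amplitude_x, "amplitude_x", lower = 0)
  check_scalar_num(amplitude_y, "amplitude_y", lower = 0)
  check_scalar_num(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar_num(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  check_scalar_num(bandwidth_hz, "bandwidth_hz", lower = 0, upper = rate_hz / 2,
                   strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_num(seed, "seed")
  structure(list(amplitude_x = amplitude_x, amplitude_y = amplitude_y,
                 bandwidth_hz = bandwidth_hz, duration_s = duration_s,
                 rate_hz = rate_hz, seed = as.integer(seed)),
            class = "sway_model_params")
}

# One axis of band-limited noise with exact sample SD = amplitude.
# The filter corner sits at 80% of the declared bandwidth so that the
# stated band contains essentially all (>95% even per realization) of
# the power despite the filter's finite roll-off.
bandlimited_axis <- function(n, bandwidth_hz, rate_hz, amplitude) {
  if (amplitude == 0) return(numeric(n))
  w <- rnorm(n)
  f <- butter_lowpass_1d(w, order = 4, cutoff_hz = 0.8 * bandwidth_hz,
                         rate_hz = rate_hz, mode = "zero_phase")
  f <- f - mean(f)
  s <- sd(f)
  if (s == 0) return(numeric(n))  # degenerate; cannot occur for n >= 2 a.s.
  f * (amplitude / s)
}

#' Simulate a ground-truth sway trajectory
#'
#' Generates a zero-mean 2-D trajectory of `round(duration_s * rate_hz)`
#' samples.  Each axis is white Gaussian noise low-pass filtered
#' (zero-phase) to `bandwidth_hz`, mean-centred, and rescaled so its
#' sample SD equals the axis amplitude exactly.  Identical parameters
#' and seed give identical output; scaling the amplitudes scales the
#' coordinates exactly linearly.
#'
#' @param params A [sway_model_params()].
#' @return A pixel-unit [trajectory()].
#' @export
simulate_sway_trajectory <- function(params) {
  stopifnot(inherits(params, "sway_model_params"))
  n <- round(params$duration_s * params$rate_hz)
  if (n < 2) stop_param("duration_s", "too short: fewer than 2 samples")
  with_seed(params$seed, {
    x <- bandlimited_axis(n, params$bandwidth_hz, params$rate_hz, params$amplitude_x)
    y <- bandlimited_axis(n, params$bandwidth_hz, params$rate_hz, params$amplitude_y)
    trajectory(x, y, params$rate_hz, units = "pixel")
  })
}

#' Rendering parameters for synthetic silhouette video
#'
#' The renderer emulates a static-camera recording of a dark trunk
#' against a plain bright background: an ellipse of `foreground_level`
#' on a `background_level` field.  A fixed sinusoidal texture pattern
#' (amplitude `texture_contrast`) is attached to the silhouette in
#' object coordinates, so it translates rigidly with it; without
#' texture, frame differencing sees only the leading and trailing edges
#' of the blob, while texture makes the interior move too and the motion
#' mask fuller.
#'
#' The silhouette edge is anti-aliased over `edge_softness_px` pixels,
#' emulating the point-spread blur of a real camera.  This matters for
#' motion detection: band-limited sway at video frame rates moves the
#' silhouette by fractions of a pixel between frames, and with a
#' hard-edged binary blob such steps change almost no pixel by more than
#' the detection threshold.  Gradual edges (and a texture whose spatial
#' gradient is steep relative to the threshold) are what make sub-pixel
#' motion visible to frame differencing, exactly as on real footage.
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param silhouette_half_width,silhouette_half_height Ellipse semi-axes
#'   in pixels.
#' @param background_level,foreground_level Intensities on \[0,1\].
#' @param texture_contrast Texture amplitude on \[0,1\];
#'   `foreground_level` plus or minus `texture_contrast` must stay in
#'   \[0,1\].  Set to 0 for a uniform blob (edge-only motion signal).
#' @param texture_period_px Spatial period of the texture in pixels.
#' @param edge_softness_px Width in pixels of the anti-aliased edge
#'   transition (0 gives a hard binary edge).
#' @param fps Frames per second of the rendered sequence.
#' @export
render_params <- function(frame_width = 64, frame_height = 96,
                          silhouette_half_width = 10,
                          silhouette_half_height = 18,
                          background_level = 0.95, foreground_level = 0.45,
                          texture_contrast = 0.45, texture_period_px = 5,
                          edge_softness_px = 1, fps = 30) {
  check_scalar_num(frame_width, "frame_width", lower = 4)
  check_scalar_num(frame_height, "frame_height", lower = 4)
  check_scalar_num(silhouette_half_width, "silhouette_half_width",
                   lower = 0, strict_lower = TRUE)
  check_scalar_num(silhouette_half_height, "silhouette_half_height",
                   lower = 0, strict_lower = TRUE)
  check_scalar_num(background_level, "background_level", lower = 0, upper = 1)
  check_scalar_num(foreground_level, "foreground_level", lower = 0, upper = 1)
  check_scalar_num(texture_contrast, "texture_contrast", lower = 0, upper = 1)
  if (foreground_level + texture_contrast > 1 ||
      foreground_level - texture_contrast < 0) {
    stop_param("texture_contrast",
               "foreground_level +/- texture_contrast must stay within [0,1]")
  }
  check_scalar_num(texture_period_px, "texture_period_px",
                   lower = 0, strict_lower = TRUE)
  check_scalar_num(edge_softness_px, "edge_softness_px", lower = 0)
  check_scalar_num(fps, "fps", lower = 0, strict_lower = TRUE)
  structure(list(frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 silhouette_half_width = silhouette_half_width,
                 silhouette_half_height = silhouette_half_height,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 texture_contrast = texture_contrast,
                 texture_period_px = texture_period_px,
                 edge_softness_px = edge_softness_px,
                 fps = fps),
            class = "render_params")
}

# Render one frame: rows x cols matrix, silhouette centred at
# (cx, cy) in 0-based pixel coordinates (x = column, y = row).
# alpha blends foreground over background across the anti-aliased edge;
# everything is a pure function of the pixel offsets (u, v) from the
# centre, so integer translations of the centre translate the image
# exactly.
render_frame <- function(cx, cy, rp) {
  cols <- seq_len(rp$frame_width) - 1
  rows <- seq_len(rp$frame_height) - 1
  u <- outer(rows * 0, cols - cx, "+")       # column offsets, rows x cols
  v <- outer(rows - cy, cols * 0, "+")       # row offsets
  rr <- sqrt((u / rp$silhouette_half_width)^2 +
             (v / rp$silhouette_half_height)^2)
  alpha <- if (rp$edge_softness_px > 0) {
    scale <- min(rp$silhouette_half_width, rp$silhouette_half_height) /
      rp$edge_softness_px
    pmin(1, pmax(0, (1 - rr) * scale + 0.5))
  } else {
    (rr <= 1) * 1
  }
  tex <- if (rp$texture_contrast > 0) {
    rp$texture_contrast *
      sin(2 * pi * u / rp$texture_period_px) *
      cos(2 * pi * v / rp$texture_period_px)
  } else 0
  frame <- rp$background_level +
    alpha * (rp$foreground_level + tex - rp$background_level)
  pmin(pmax(frame, 0), 1)
}

#' Render a silhouette video from a sway trajectory
#'
#' Produces one frame per trajectory sample.  The trajectory is read as
#' an offset from the frame centre: the silhouette centre for sample i
#' is `(frame_width/2 + x[i], frame_height/2 + y[i])` in 0-based pixel
#' coordinates.  An error is raised (naming the first offending sample)
#' if the silhouette would leave the frame.
#'
#' @param traj A pixel-unit [trajectory()] of centre offsets.
#' @param render A [render_params()].
#' @return A [frame_sequence()] with `fps = render$fps`.
#' @export
render_silhouette_video <- function(traj, render = render_params()) {
  stopifnot(inherits(traj, "sway_trajectory"), inherits(render, "render_params"))
  if (traj$units != "pixel") stop_param("traj", "must be in pixel units")
  cx <- render$frame_width / 2 + traj$x
  cy <- render$frame_height / 2 + traj$y
  # the anti-aliased edge extends slightly beyond the nominal semi-axes
  soft_scale <- if (render$edge_softness_px > 0) {
    0.5 * render$edge_softness_px /
      min(render$silhouette_half_width, render$silhouette_half_height)
  } else 0
  ext_x <- render$silhouette_half_width * (1 + soft_scale)
  ext_y <- render$silhouette_half_height * (1 + soft_scale)
  bad <- which(cx - ext_x < 0 |
               cx + ext_x > render$frame_width - 1 |
               cy - ext_y < 0 |
               cy + ext_y > render$frame_height - 1)
  if (length(bad)) {
    stop(sprintf("silhouette exits the frame at sample %d (0-based %d)",
                 bad[1], bad[1] - 1L), call. = FALSE)
  }
  n <- length(traj$x)
  frames <- array(0, dim = c(render$frame_height, render$frame_width, n))
  for (i in seq_len(n)) {
    frames[, , i] <- render_frame(cx[i], cy[i], render)
  }
  frame_sequence(frames, fps = render$fps)
}

#' Simulate a coupled COP recording from a COM trajectory
#'
#' Emulates the force-plate view of the same sway: the COM trajectory is
#' resampled to `rate_hz` (default 100 Hz) by linear interpolation,
#' scaled from pixels to millimetres, and corrupted by independent
#' Gaussian coupling noise plus a supra-cutoff sinusoidal tremor that
#' the Butterworth conditioning stage should largely remove.  The
#' coupling noise SD is the dial that sets the ground-truth strength of
#' the video-COP association.
#'
#' @param com A [trajectory()] (pixel units) of the simulated COM.
#' @param pixel_to_mm Positive scale factor (mm per pixel).
#' @param coupling_noise_sd SD in mm of the additive noise decoupling
#'   COP from COM (default 0).
#' @param tremor_amplitude Amplitude in mm of the high-frequency
#'   sinusoidal component (default 0).
#' @param tremor_hz Tremor frequency in Hz (default 30; must exceed the
#'   10 Hz conditioning cutoff to be removed by filtering).
#' @param rate_hz Output sampling rate (default 100).
#' @param seed Integer RNG seed for the coupling noise.
#' @return A [cop_recording()].
#' @export
simulate_cop_from_com <- function(com, pixel_to_mm = 1,
                                  coupling_noise_sd = 0,
                                  tremor_amplitude = 0, tremor_hz = 30,
                                  rate_hz = 100, seed = 1L) {
  stopifnot(inherits(com, "sway_trajectory"))
  if (length(com$x) < 2L) stop("COM trajectory needs at least 2 samples", call. = FALSE)
  check_scalar_num(pixel_to_mm, "pixel_to_mm", lower = 0, strict_lower = TRUE)
  check_scalar_num(coupling_noise_sd, "coupling_noise_sd", lower = 0)
  check_scalar_num(tremor_amplitude, "tremor_amplitude", lower = 0)
  n_in <- length(com$x)
  t_in <- (seq_len(n_in) - 1) / com$rate_hz
  t_out <- seq(0, t_in[n_in], by = 1 / rate_hz)
  x <- approx(t_in, com$x, xout = t_out)$y * pixel_to_mm
  y <- approx(t_in, com$y, xout = t_out)$y * pixel_to_mm
  with_seed(seed, {
    if (coupling_noise_sd > 0) {
      x <- x + rnorm(length(x), sd = coupling_noise_sd)
      y <- y + rnorm(length(y), sd = coupling_noise_sd)
    }
    if (tremor_amplitude > 0) {
      x <- x + tremor_amplitude * sin(2 * pi * tremor_hz * t_out)
      y <- y + tremor_amplitude * cos(2 * pi * tremor_hz * t_out)
    }
    cop_recording(x, y, rate_hz,
                  subject_id = NA_character_, condition = NA_character_)
  })
}

#' Specification of a synthetic two-group cohort
#'
#' Mirrors a two-group (atypical vs control), four-condition
#' quiet-stance design: conditions cross eyes open/closed with feet
#' apart/together, and the atypical ("cp") group sways more by a
#' multiplicative amplitude factor.
#'
#' @param n_cp,n_control Group sizes (>= 0).
#' @param cp_amplitude_multiplier Factor (> 0, typically > 1) scaling
#'   the sway amplitudes of the cp-like group (default 2).
#' @param condition_multipliers Four positive factors scaling sway per
#'   stance condition, in the order eyes-open/feet-apart,
#'   eyes-closed/feet-apart, eyes-open/feet-together,
#'   eyes-closed/feet-together.  Defaults increase with postural
#'   difficulty.
#' @param coupling_noise_sd SD in mm of the COP coupling noise
#'   (default 1).
#' @param tremor_amplitude Tremor amplitude in mm passed through to
#'   [simulate_cop_from_com()] (default 0.5).
#' @param pixel_to_mm Video-to-plate scale factor (default 2 mm/px).
#' @param subject_amplitude_sdlog SD (log scale) of a per-subject
#'   multiplicative amplitude factor, constant across a subject's four
#'   trials (default 0.35, truncated at +/- 2 SD).  Real cohorts vary
#'   between subjects; without this trait-like heterogeneity the true
#'   between-subject variance within a group is zero and correlation
#'   estimates across the cohort are degenerate.  Set to 0 for
#'   identical subjects.
#' @param seed Integer master seed; all per-trial seeds derive from it.
#' @export
cohort_spec <- function(n_cp = 20, n_control = 20,
                        cp_amplitude_multiplier = 2,
                        condition_multipliers = c(1, 1.3, 1.6, 2),
                        coupling_noise_sd = 1, tremor_amplitude = 0.5,
                        pixel_to_mm = 2, subject_amplitude_sdlog = 0.35,
                        seed = 1L) {
  check_scalar_num(n_cp, "n_cp", lower = 0)
  check_scalar_num(n_control, "n_control", lower = 0)
  check_scalar_num(cp_amplitude_multiplier, "cp_amplitude_multiplier",
                   lower = 0, strict_lower = TRUE)
  if (length(condition_multipliers) != 4L || any(condition_multipliers <= 0)) {
    stop_param("condition_multipliers", "must be 4 positive factors")
  }
  check_scalar_num(coupling_noise_sd, "coupling_noise_sd", lower = 0)
  check_scalar_num(tremor_amplitude, "tremor_amplitude", lower = 0)
  check_scalar_num(pixel_to_mm, "pixel_to_mm", lower = 0, strict_lower = TRUE)
  check_scalar_num(subject_amplitude_sdlog, "subject_amplitude_sdlog", lower = 0)
  structure(list(n_cp = as.integer(n_cp), n_control = as.integer(n_control),
                 cp_amplitude_multiplier = cp_amplitude_multiplier,
                 condition_multipliers = condition_multipliers,
                 coupling_noise_sd = coupling_noise_sd,
                 tremor_amplitude = tremor_amplitude,
                 pixel_to_mm = pixel_to_mm,
                 subject_amplitude_sdlog = subject_amplitude_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Condition labels of the four-condition quiet-stance protocol
#' @export
stance_conditions <- function() {
  c("EO_apart", "EC_apart", "EO_together", "EC_together")
}

#' Generate a paired synthetic cohort
#'
#' For every subject x condition, simulates a ground-truth COM
#' trajectory, a coupled COP recording, and (optionally) a rendered
#' silhouette video.  cp-group subjects use amplitudes scaled by
#' `cp_amplitude_multiplier`; condition c scales by
#' `condition_multipliers[c]`.  Per-trial seeds are drawn once from the
#' master seed, so the whole cohort is reproducible from
#' `(spec, base, render)`.
#'
#' @param spec A [cohort_spec()].
#' @param base A [sway_model_params()] giving control-group,
#'   easiest-condition amplitudes and the trial duration / frame rate.
#' @param render A [render_params()], or `NULL` to skip video rendering
#'   (trajectories and COP only; much faster for statistical
#'   simulations).
#' @return A list with `trials` (a list, one element per trial, each
#'   holding `subject_id`, `group`, `condition`, `seed`, `traj`, `cop`
#'   and optionally `video`) and `manifest` (a data frame, one row per
#'   trial, with the true amplitudes).
#' @export
generate_cohort <- function(spec = cohort_spec(), base = sway_model_params(),
                            render = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(base, "sway_model_params"))
  conds <- stance_conditions()
  groups <- c(rep("cp", spec$n_cp), rep("control", spec$n_control))
  n_subj <- length(groups)
  n_trials <- n_subj * length(conds)
  if (n_trials == 0L) {
    return(list(trials = list(), manifest = data.frame()))
  }
  drawn <- with_seed(spec$seed, {
    list(trial_seeds = sample.int(.Machine$integer.max - 1L, n_trials),
         # trait-like per-subject amplitude factor, truncated at +/-2 SD
         subj_factor = exp(pmin(pmax(rnorm(n_subj, sd = spec$subject_amplitude_sdlog),
                                     -2 * spec$subject_amplitude_sdlog),
                                2 * spec$subject_amplitude_sdlog)))
  })
  trial_seeds <- drawn$trial_seeds
  trials <- vector("list", n_trials)
  rows <- vector("list", n_trials)
  k <- 0L
  for (s in seq_len(n_subj)) {
    gmul <- drawn$subj_factor[s] *
      if (groups[s] == "cp") spec$cp_amplitude_multiplier else 1
    sid <- sprintf("S%03d", s)
    for (ci in seq_along(conds)) {
      k <- k + 1L
      mul <- gmul * spec$condition_multipliers[ci]
      p <- sway_model_params(amplitude_x = base$amplitude_x * mul,
                             amplitude_y = base$amplitude_y * mul,
                             bandwidth_hz = base$bandwidth_hz,
                             duration_s = base$duration_s,
                             rate_hz = base$rate_hz,
                             seed = trial_seeds[k])
      traj <- simulate_sway_trajectory(p)
      if (!is.null(render)) {
        # Gaussian tails can occasionally exceed the frame margin; shrink
        # the whole trial minimally so the silhouette always fits.  The
        # rescaled trajectory IS the trial's ground truth (the COP below
        # is generated from it), so pipeline comparisons stay exact.
        soft_scale <- if (render$edge_softness_px > 0) {
          0.5 * render$edge_softness_px /
            min(render$silhouette_half_width, render$silhouette_half_height)
        } else 0
        margin_x <- render$frame_width / 2 - 1 -
          render$silhouette_half_width * (1 + soft_scale)
        margin_y <- render$frame_height / 2 - 1 -
          render$silhouette_half_height * (1 + soft_scale)
        if (margin_x <= 0 || margin_y <= 0) {
          stop_param("render", "silhouette does not fit in the frame at all")
        }
        over <- max(max(abs(traj$x)) / margin_x, max(abs(traj$y)) / margin_y)
        if (over > 1) {
          traj$x <- traj$x / over
          traj$y <- traj$y / over
        }
      }
      cop <- simulate_cop_from_com(traj, pixel_to_mm = spec$pixel_to_mm,
                                   coupling_noise_sd = spec$coupling_noise_sd,
                                   tremor_amplitude = spec$tremor_amplitude,
                                   seed = trial_seeds[k] + 1L)
      cop$subject_id <- sid
      cop$condition <- conds[ci]
      trial <- list(subject_id = sid, group = groups[s],
                    condition = conds[ci], seed = trial_seeds[k],
                    traj = traj, cop = cop)
      if (!is.null(render)) {
        trial$video <- render_silhouette_video(traj, render)
      }
      trials[[k]] <- trial
      rows[[k]] <- data.frame(subject_id = sid, group = groups[s],
                              condition = conds[ci], seed = trial_seeds[k],
                              amplitude_x = p$amplitude_x,
                              amplitude_y = p$amplitude_y,
                              stringsAsFactors = FALSE)
    }
  }
  list(trials = trials, manifest = do.call(rbind, rows))
}
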