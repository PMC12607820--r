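test_that("sway simulation honours amplitude, zero mean, and determinism", {
  p0 <- sway_model_params(amplitude_x = 0, amplitude_y = 0, bandwidth_hz = 1,
                          duration_s = 2, rate_hz = 30, seed = 1)
  tr0 <- simulate_sway_trajectory(p0)
  expect_true(all(tr0$x == 0) && all(tr0$y == 0))

  p <- sway_model_params(amplitude_x = 10, amplitude_y = 4, bandwidth_hz = 1,
                         duration_s = 30, rate_hz = 30, seed = 1)
  tr <- simulate_sway_trajectory(p)
  expect_equal(length(tr$x), 900)
  expect_equal(sd(tr$x), 10, tolerance = 1e-6)
  expect_equal(sd(tr$y), 4, tolerance = 1e-6)
  expect_equal(mean(tr$x), 0, tolerance = 1e-9)

  tr_again <- simulate_sway_trajectory(p)
  expect_identical(tr, tr_again)
  p2 <- sway_model_params(amplitude_x = 10, amplitude_y = 4, bandwidth_hz = 1,
                          duration_s = 30, rate_hz = 30, seed = 2)
  expect_false(identical(simulate_sway_trajectory(p2)$x, tr$x))
})

test_that("amplitude scaling is exactly linear in the coordinates", {
  p1 <- sway_model_params(amplitude_x = 2, amplitude_y = 3, bandwidth_hz = 1,
                          duration_s = 10, rate_hz = 30, seed = 5)
  p3 <- sway_model_params(amplitude_x = 6, amplitude_y = 9, bandwidth_hz = 1,
                          duration_s = 10, rate_hz = 30, seed = 5)
  t1 <- simulate_sway_trajectory(p1)
  t3 <- simulate_sway_trajectory(p3)
  expect_equal(t3$x, 3 * t1$x, tolerance = 1e-12)
  expect_equal(t3$y, 3 * t1$y, tolerance = 1e-12)
})

test_that("generated sway is band-limited: >95% of power below the bandwidth", {
  p <- sway_model_params(amplitude_x = 5, amplitude_y = 5, bandwidth_hz = 2,
                         duration_s = 30, rate_hz = 100, seed = 3)
  tr <- simulate_sway_trajectory(p)
  spec <- stats::spec.pgram(tr$x, plot = FALSE, taper = 0, detrend = FALSE)
  freq_hz <- spec$freq * p$rate_hz
  frac_below <- sum(spec$spec[freq_hz <= p$bandwidth_hz]) / sum(spec$spec)
  expect_gt(frac_below, 0.95)
})

test_that("simulation rejects invalid model parameters by field name", {
  expect_error(sway_model_params(amplitude_x = -1), "amplitude_x")
  expect_error(sway_model_params(bandwidth_hz = 20, rate_hz = 30), "bandwidth_hz")
  expect_error(sway_model_params(duration_s = 0), "duration_s")
})

test_that("constant trajectory renders pixel-identical frames", {
  tr <- trajectory(rep(0, 4), rep(0, 4), 30)
  v <- render_silhouette_video(tr, render_params())
  for (i in 2:4) expect_identical(v$frames[, , i], v$frames[, , 1])
})

test_that("integer translation of the trajectory translates the rendered frame", {
  tr <- trajectory(c(0, 5), c(0, 0), 30)
  rp <- render_params(frame_width = 64, frame_height = 96)
  v <- render_silhouette_video(tr, rp)
  f1 <- v$frames[, , 1]; f2 <- v$frames[, , 2]
  # frame 2 equals frame 1 shifted 5 columns right, over the common support
  expect_equal(f2[, 6:64], f1[, 1:59], tolerance = 1e-12)
})

test_that("without texture, frame difference is confined to edge bands", {
  rp <- render_params(frame_width = 64, frame_height = 64,
                      silhouette_half_width = 10, silhouette_half_height = 10,
                      texture_contrast = 0, edge_softness_px = 0)
  tr <- trajectory(c(0, 2), c(0, 0), 30)
  v <- render_silhouette_video(tr, rp)
  d <- abs(v$frames[, , 2] - v$frames[, , 1])
  changed <- which(d > 1e-12, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  # all changed pixels lie inside one ellipse but outside the other
  cx1 <- 32; cx2 <- 34; cy <- 32
  u1 <- (changed[, 2] - 1 - cx1) / 10; v1 <- (changed[, 1] - 1 - cy) / 10
  u2 <- (changed[, 2] - 1 - cx2) / 10; v2 <- v1
  in1 <- u1^2 + v1^2 <= 1
  in2 <- u2^2 + v2^2 <= 1
  expect_true(all(xor(in1, in2)))
  # interior common to both positions is unchanged
  expect_false(any(in1 & in2))
})

test_that("renderer reports the first sample at which the silhouette exits", {
  rp <- render_params(frame_width = 64, frame_height = 96)
  tr <- trajectory(c(0, 100, 0), rep(0, 3), 30)
  expect_error(render_silhouette_video(tr, rp), "sample 2")
})

test_that("rendered support centroid tracks the true position within 1 px", {
  p <- sway_model_params(amplitude_x = 5, amplitude_y = 5, bandwidth_hz = 1,
                         duration_s = 3, rate_hz = 30, seed = 4)
  tr <- simulate_sway_trajectory(p)
  rp <- render_params(frame_width = 96, frame_height = 128,
                      silhouette_half_width = 8, silhouette_half_height = 14)
  v <- render_silhouette_video(tr, rp)
  for (i in seq_len(dim(v$frames)[3])) {
    support <- abs(v$frames[, , i] - rp$background_level) > 1e-9
    cen <- reference_centroid(support)
    expect_lt(abs(cen["x"] - (48 + tr$x[i])), 1)
    expect_lt(abs(cen["y"] - (64 + tr$y[i])), 1)
  }
})

test_that("COP coupling is the identity in the noise-free matched-rate case", {
  tr <- trajectory(sin(seq(0, 5, length.out = 501)),
                   cos(seq(0, 5, length.out = 501)), rate_hz = 100)
  cop <- simulate_cop_from_com(tr, pixel_to_mm = 1, coupling_noise_sd = 0,
                               tremor_amplitude = 0, seed = 1)
  expect_equal(cop$x_mm, tr$x, tolerance = 1e-12)
  expect_equal(cop$y_mm, tr$y, tolerance = 1e-12)
  expect_equal(cop$rate_hz, 100)

  cop2 <- simulate_cop_from_com(tr, pixel_to_mm = 2, coupling_noise_sd = 0,
                                tremor_amplitude = 0, seed = 1)
  expect_equal(cop2$x_mm, 2 * tr$x, tolerance = 1e-12)
})

test_that("simulated tremor above the cutoff is removed by conditioning", {
  p <- sway_model_params(amplitude_x = 5, amplitude_y = 5, bandwidth_hz = 1,
                         duration_s = 30, rate_hz = 30, seed = 6)
  tr <- simulate_sway_trajectory(p)
  cop <- simulate_cop_from_com(tr, pixel_to_mm = 1, coupling_noise_sd = 0,
                               tremor_amplitude = 5, tremor_hz = 30, seed = 2)
  filt <- butterworth_lowpass(cop)
  t <- (seq_along(filt$x_mm) - 1) / 100
  i <- 500:2500
  fit <- lm(filt$x_mm[i] ~ sin(2 * pi * 30 * t[i]) + cos(2 * pi * 30 * t[i]))
  residual_amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(residual_amp, 0.1)
})

test_that("cohort structure, labelling and reproducibility are exact", {
  spec <- cohort_spec(n_cp = 0, n_control = 1, seed = 1)
  base <- sway_model_params(duration_s = 2)
  co <- generate_cohort(spec, base)
  expect_length(co$trials, 4)
  expect_true(all(co$manifest$group == "control"))
  expect_setequal(co$manifest$condition, stance_conditions())

  spec2 <- cohort_spec(n_cp = 2, n_control = 2, seed = 9)
  co_a <- generate_cohort(spec2, base)
  co_b <- generate_cohort(spec2, base)
  expect_identical(co_a$manifest, co_b$manifest)
  expect_identical(co_a$trials[[3]]$traj, co_b$trials[[3]]$traj)
  expect_identical(co_a$trials[[3]]$cop, co_b$trials[[3]]$cop)
})

test_that("doubling the cp amplitude multiplier doubles mean cp path length", {
  base <- sway_model_params(amplitude_x = 3, amplitude_y = 3, bandwidth_hz = 1,
                            duration_s = 10, rate_hz = 30)
  # identical subjects isolate the group effect from trait heterogeneity
  spec <- cohort_spec(n_cp = 20, n_control = 20, cp_amplitude_multiplier = 2,
                      subject_amplitude_sdlog = 0, coupling_noise_sd = 0,
                      tremor_amplitude = 0, seed = 31)
  co <- generate_cohort(spec, base)
  path_len <- vapply(co$trials, function(t) {
    compute_sway_parameters(t$traj)$ctotal_r
  }, numeric(1))
  grp <- vapply(co$trials, `[[`, "", "group")
  ratio <- mean(path_len[grp == "cp"]) / mean(path_len[grp == "control"])
  expect_equal(ratio, 2, tolerance = 0.1)
})
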