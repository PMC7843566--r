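test_that("flat waveform with no motion or noise renders identical frames", {
  ph <- scene_phantom(frame_shape = c(64L, 64L), onh_radius = 18)
  art <- motion_artifact_spec(n = 10, seed = 3)
  rv <- render_video(ph, rep(0, 10), art)
  for (i in 2:10)
    expect_identical(rv$video$frames[, , i], rv$video$frames[, , 1])
})

test_that("rendered grey levels follow the multiplicative absorption model", {
  ph <- scene_phantom(frame_shape = c(64L, 64L), onh_radius = 18,
                      texture_amp = 0)
  art <- motion_artifact_spec(n = 3, seed = 3)
  a <- c(0, 2.5, 5)
  rv <- render_video(ph, a, art)
  tissue <- rv$truth$roi$mask
  vessels <- rv$truth$vessels$mask
  surround <- !rv$truth$onh$mask & !vessels
  for (i in 1:3) {
    f <- rv$video$frames[, , i]
    expect_equal(unique(round(f[tissue], 9)),
                 round(220 * (1 - a[i] / 100), 9))
    expect_equal(unique(round(f[vessels], 9)), round(220 * 0.45, 9))
    expect_equal(unique(round(f[surround], 9)), round(220 * 0.65, 9))
  }
})

test_that("rendering is bit-identical under the same seed", {
  ph <- scene_phantom(frame_shape = c(64L, 64L), onh_radius = 18)
  wave <- rep(c(0, 3, 5, 2), 3)
  art <- motion_artifact_spec(dx = sin(1:12), dy = cos(1:12), n = 12,
                              blink_frames = 4L, blur_frames = 8L,
                              noise_sd = 2, seed = 99)
  rv1 <- render_video(ph, wave, art)
  rv2 <- render_video(ph, wave, art)
  expect_identical(rv1$video$frames, rv2$video$frames)
  rv3 <- render_video(ph, wave, motion_artifact_spec(
    dx = sin(1:12), dy = cos(1:12), n = 12, blink_frames = 4L,
    blur_frames = 8L, noise_sd = 2, seed = 100))
  expect_false(identical(rv1$video$frames, rv3$video$frames))
})

test_that("the pipeline's signal stage inverts the forward model", {
  # no motion, no noise, gain 1: the ROI-mean trace must return the
  # injected waveform's excursion
  pv <- make_phantom_video(n_frames = 125, amplitude = 5, noise_sd = 0,
                           texture_amp = 0)
  i_raw <- extract_intensity_signal(pv$video, pv$truth$roi)
  # exactly 3 beat periods (75 frames, odd): boxcar null at the pulse rate
  i_trend <- estimate_trend(i_raw, fps = 25, window_s = 3.0)
  sig <- compute_pleth_signal(i_raw, i_trend, fps = 25)
  # ratio at systole: intensity dips by exactly amplitude percent
  expect_equal(min(i_raw) / max(i_raw), 0.95, tolerance = 2e-4)
  # the trend sits below the diastolic baseline by the beat-mean
  # absorption, so A = 1 - I/I_avg rescales the excursion by
  # 1 / (1 - mean(a)/100); this is the definition's exact output
  expected <- diff(range(pv$wave)) / (1 - mean(pv$wave) / 100)
  interior <- 38:88                # windows here never touch the padding
  expect_equal(diff(range(sig$a_pct[interior])), expected, tolerance = 0.01)
})

test_that("render_video validates its contract", {
  ph <- scene_phantom(frame_shape = c(64L, 64L), onh_radius = 18)
  expect_error(render_video(ph, rep(0, 5), motion_artifact_spec(n = 4)),
               "length")
  expect_error(scene_phantom(frame_shape = c(64L, 64L), onh_radius = 40),
               "inside the frame")
  expect_error(scene_phantom(frame_shape = c(64L, 64L), onh_radius = 18,
                             vessel_tree = list(list(from = c(1, 1),
                                                     to = c(60, 60),
                                                     width = 0.5))),
               "width")
  expect_error(scene_phantom(surround_absorption = 1.2), "absorption")
})

test_that("blink frames render near-saturated and blur frames lose detail", {
  ph <- scene_phantom(frame_shape = c(64L, 64L), onh_radius = 18)
  art <- motion_artifact_spec(n = 6, blink_frames = 2L, blur_frames = 5L,
                              seed = 5)
  rv <- render_video(ph, rep(2, 6), art)
  expect_gt(mean(rv$video$frames[, , 2]), 240)
  grad <- function(f) mean(diff(f)^2)
  expect_lt(grad(rv$video$frames[, , 5]), 0.2 * grad(rv$video$frames[, , 1]))
})
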