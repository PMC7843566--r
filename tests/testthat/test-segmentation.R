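test_that("average_frames reduces noise by sqrt(N) and skips artifacts", {
  ph <- scene_phantom()
  rv <- render_video(ph, rep(0, 4), motion_artifact_spec(n = 4, seed = 2))
  expect_equal(average_frames(rv$video), rv$video$frames[, , 1])
  # noise-averaging law on a flat surround region
  pv2 <- make_phantom_video(n_frames = 250, amplitude = 0.01, noise_sd = 8,
                            texture_amp = 0)
  avg2 <- average_frames(pv2$video)
  flat <- !pv2$truth$onh$mask & !pv2$truth$vessels$mask
  flat <- flat & row(avg2) > 5 & row(avg2) < 95 & col(avg2) > 5 & col(avg2) < 95
  expect_equal(sd(avg2[flat]), 8 / sqrt(250), tolerance = 0.35)
  # blink frames do not perturb the average
  pv3 <- make_phantom_video(n_frames = 40, noise_sd = 2, seed = 21)
  v_blink <- pv3$video
  v_blink$frames[, , c(10, 11)] <- 250
  v_blink$flags[c(10, 11)] <- "blink"
  avg_ref <- average_frames(pv3$video)
  avg_blink <- average_frames(v_blink)
  # the two averages differ only through the two dropped noise realizations
  expect_lt(max(abs(avg_blink - avg_ref)), 1.5)
  expect_error(average_frames(video_sequence(pv3$video$frames, 25,
                                             rep("blink", 40))),
               "no artifact-free")
})

test_that("segment_onh validates manual masks and passes them through", {
  pv <- make_phantom_video(n_frames = 4, noise_sd = 0)
  avg <- average_frames(pv$video)
  manual <- pv$truth$onh
  out <- segment_onh(avg, manual_mask = manual)
  expect_identical(out$mask, manual$mask)
  expect_identical(out$provenance, "manual")
  empty <- roi_mask(matrix(FALSE, 100, 100), "onh", "manual")
  expect_error(segment_onh(avg, manual_mask = empty), "empty")
  two <- matrix(FALSE, 100, 100); two[2:4, 2:4] <- TRUE; two[60:62, 60:62] <- TRUE
  expect_error(segment_onh(avg, roi_mask(two, "onh", "manual")),
               "single connected component")
  expect_error(segment_onh(avg[1:50, ], manual_mask = manual), "shape")
})

test_that("automatic ONH segmentation reaches Dice >= 0.95 on a clean phantom", {
  pv <- make_phantom_video(n_frames = 4, noise_sd = 0)
  avg <- average_frames(pv$video)
  auto <- segment_onh(avg)
  expect_identical(auto$provenance, "automatic")
  truth <- pv$truth$onh$mask
  dice <- 2 * sum(auto$mask & truth) / (sum(auto$mask) + sum(truth))
  expect_gte(dice, 0.95)
})

test_that("vessel segmentation finds dark polylines and nothing else", {
  pv <- make_phantom_video(n_frames = 4, noise_sd = 0)
  avg <- average_frames(pv$video)
  v <- segment_vessels(avg)
  truth <- pv$truth$vessels$mask
  hit <- EBImage::dilate(v$mask * 1, onhpleth:::.disc_kernel(1)) > 0
  expect_gte(sum(hit & truth) / sum(truth), 0.8)  # recall at 1 px tolerance
  # vessel-free phantom: near-empty mask
  ph0 <- scene_phantom(frame_shape = c(100L, 100L), onh_radius = 30,
                       vessel_tree = list())
  rv0 <- render_video(ph0, rep(0, 4), motion_artifact_spec(n = 4, seed = 2))
  v0 <- segment_vessels(average_frames(rv0$video))
  expect_lt(mean(v0$mask), 0.005)
  # constant image: empty
  vc <- segment_vessels(matrix(100, 80, 80))
  expect_false(any(vc$mask))
})

test_that("disc dilation matches the Euclidean offset-set definition", {
  empty <- roi_mask(matrix(FALSE, 32, 32), "vessels", "automatic")
  expect_false(any(dilate_vessels(empty)$mask))
  # single pixel -> 13-px Euclidean disc of radius 2
  one <- matrix(FALSE, 21, 21); one[11, 11] <- TRUE
  d1 <- dilate_vessels(roi_mask(one, "vessels", "manual"))$mask
  expect_equal(sum(d1), 13)
  offs <- which(d1, arr.ind = TRUE) - 11
  expect_true(all(offs[, 1]^2 + offs[, 2]^2 <= 4))
  # oracle equivalence and monotonicity on random masks
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(runif(64 * 64) < 0.02, 64, 64)
    lib <- dilate_vessels(roi_mask(m, "vessels", "manual"))$mask
    expect_identical(lib, oracle_dilate(m, 2))
    expect_true(all(lib[m]))                       # extensive
    sub <- m & (matrix(runif(64 * 64), 64, 64) < 0.5)
    libsub <- dilate_vessels(roi_mask(sub, "vessels", "manual"))$mask
    expect_true(all(lib[libsub]))                  # monotone
  }
  # radius reading of the element size
  d5 <- dilate_vessels(roi_mask(one, "vessels", "manual"), size_px = 5,
                       interpret = "radius")$mask
  expect_equal(sum(d5), sum(oracle_dilate(one, 5)))
})

test_that("the tissue ROI is the ONH minus dilated vessels, or errors", {
  pv <- make_phantom_video(n_frames = 4, noise_sd = 0)
  onh <- pv$truth$onh
  vd <- dilate_vessels(pv$truth$vessels)
  roi <- make_onh_roi(onh, vd)
  expect_identical(roi$mask, onh$mask & !vd$mask)   # set-arithmetic oracle
  expect_false(any(roi$mask & vd$mask))
  expect_true(all(onh$mask[roi$mask]))
  # empty vessel mask: ROI equals the ONH mask
  noves <- roi_mask(matrix(FALSE, 100, 100), "vessels_dilated", "automatic")
  expect_identical(make_onh_roi(onh, noves)$mask, onh$mask)
  # vessels covering the whole disc: hard failure
  allv <- roi_mask(matrix(TRUE, 100, 100), "vessels_dilated", "automatic")
  expect_error(make_onh_roi(onh, allv), "noise-dominated")
})
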