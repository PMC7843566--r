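test_that("minima detection finds the troughs of a sampled sinusoid", {
  t <- (0:249) / 25
  sig <- make_sig(3 + 3 * sin(2 * pi * t))          # 1 Hz, 10 s
  m <- detect_minima(sig)
  expect_true(length(m) %in% c(9L, 10L))
  expect_true(all(abs(diff(m) - 25) <= 1))
  expect_length(detect_minima(make_sig(rep(1, 100))), 0)
  # a blink-flagged trough is excluded
  fl <- rep("ok", 250); fl[m[4] + (-1:1)] <- "blink"
  m2 <- detect_minima(make_sig(3 + 3 * sin(2 * pi * t), flags = fl))
  expect_false(m[4] %in% m2)
  expect_true(all(setdiff(m, m[4]) %in% m2))
})

test_that("pulse selection keeps clean beats and names its rejections", {
  beat <- waveform_value(waveform_spec(5, 0.3, 1.0), (0:24) / 25)
  a <- c(rep(beat, 6), 0)
  sig <- make_sig(a)
  minima <- seq(1, 151, by = 25)
  lab <- select_pulses(minima, sig)
  expect_equal(nrow(onhpleth:::.label_beats(lab)), 6)
  # beat spanning a blink frame is rejected with the reason recorded
  fl <- rep("ok", length(a)); fl[60] <- "blink"
  lab2 <- select_pulses(minima, make_sig(a, flags = fl))
  expect_equal(nrow(onhpleth:::.label_beats(lab2)), 5)
  rej <- attr(lab2, "rejected")
  expect_identical(rej$reason, "flagged frame")
  expect_true(rej$start <= 60 && rej$end >= 60)
  # fewer than two surviving beats is a failure naming the rejects
  fl3 <- rep("ok", length(a)); fl3[c(10, 35, 60, 85, 110)] <- "blur"
  expect_error(select_pulses(minima, make_sig(a, flags = fl3)),
               "flagged frame")
  # non-monotone manual labels fail validation
  expect_error(pulse_labels(c(10, 5, 30), fps = 25), "increasing")
  expect_error(pulse_labels(c(10, 12), fps = 25), "minimum beat period")
})

test_that("more than max_pulses surviving beats are capped", {
  beat <- waveform_value(waveform_spec(5, 0.3, 1.0), (0:24) / 25)
  sig <- make_sig(c(rep(beat, 9), 0))
  lab <- select_pulses(seq(1, 226, by = 25), sig)
  expect_equal(nrow(onhpleth:::.label_beats(lab)), 7)
})

test_that("pulse averaging re-references, resamples and pools correctly", {
  beat <- waveform_value(waveform_spec(5, 0.3, 1.0), (0:24) / 25)
  sig <- make_sig(c(rep(beat, 4), 0) + 2)           # constant offset
  lab <- pulse_labels(seq(1, 101, by = 25), fps = 25)
  ap <- average_pulses(sig, lab)
  expect_equal(ap$n_pulses, 4L)
  expect_equal(ap$values[1], 0)                      # start-referenced
  expect_equal(max(ap$sd), 0)
  expect_equal(ap$values, c(beat, 0), tolerance = 1e-10)
  expect_equal(ap$duration_s, 1.0)
  # two triangle pulses with amplitudes 4 and 6
  b4 <- waveform_value(waveform_spec(4, 0.32, 1.0), (0:24) / 25)
  b6 <- waveform_value(waveform_spec(6, 0.32, 1.0), (0:24) / 25)
  sig2 <- make_sig(c(b4, b6, 0))
  ap2 <- average_pulses(sig2, pulse_labels(c(1, 26, 51), fps = 25))
  expect_equal(peak_amplitude(ap2), 5)
  k <- which.max(ap2$values)
  expect_equal(ap2$sd[k], sd(c(4, 6)))
  # beats of 24 and 26 frames: L = 25 samples, duration 1.0 s
  b24 <- waveform_value(waveform_spec(5, 0.3, 0.96), (0:23) / 25)
  b26 <- waveform_value(waveform_spec(5, 0.3, 1.04), (0:25) / 25)
  sig3 <- make_sig(c(b24, b26, 0))
  ap3 <- average_pulses(sig3, pulse_labels(c(1, 25, 51), fps = 25))
  expect_equal(ap3$duration_s, 1.0)
  expect_length(ap3$values, 26)                      # 25 intervals
  # single pulse: allowed only when min_pulses = 1, with zero SD
  expect_error(average_pulses(sig2, pulse_labels(c(1, 26), fps = 25)), ">= 2")
  expect_warning(
    ap1 <- average_pulses(sig2, pulse_labels(c(1, 26), fps = 25),
                          min_pulses = 1L), "single beat")
  expect_equal(max(ap1$sd), 0)
})

test_that("averaging is invariant to beat order", {
  b4 <- waveform_value(waveform_spec(4, 0.32, 1.0), (0:24) / 25)
  b6 <- waveform_value(waveform_spec(6, 0.32, 1.0), (0:24) / 25)
  b5 <- waveform_value(waveform_spec(5, 0.32, 1.0), (0:24) / 25)
  sig <- make_sig(c(b4, b6, b5, 0))
  lab <- pulse_labels(c(1, 26, 51, 76), fps = 25)
  ap <- average_pulses(sig, lab)
  labr <- lab
  labr$beats <- onhpleth:::.label_beats(lab)[c(3, 1, 2), ]
  apr <- average_pulses(sig, labr)
  expect_equal(ap$values, apr$values)
  expect_equal(ap$sd, apr$sd)
})

test_that("pulse rate follows the mean beat interval", {
  expect_equal(pulse_rate(pulse_labels(seq(1, 226, by = 25), fps = 25)), 60)
  expect_equal(pulse_rate(pulse_labels(seq(1, 201, by = 20), fps = 25)), 75)
  expect_equal(pulse_rate(pulse_labels(c(1, 25, 51), fps = 25)), 60)
})

test_that("label files round-trip and refuse diagnosis fields", {
  lab <- pulse_labels(c(1, 26, 50, 77), fps = 25, source = "manual")
  f <- tempfile(fileext = ".json")
  write_pulse_labels(lab, f, sequence_id = "seq01")
  back <- read_pulse_labels(f)
  expect_equal(back$minima_frames, lab$minima_frames)
  expect_identical(back$source, "manual")
  expect_identical(attr(back, "sequence_id"), "seq01")
  bad <- jsonlite::read_json(f, simplifyVector = TRUE)
  bad$diagnosis <- "perim"
  jsonlite::write_json(bad, f, auto_unbox = TRUE)
  expect_error(read_pulse_labels(f), "diagnosis")
})
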