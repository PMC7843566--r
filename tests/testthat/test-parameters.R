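dense_triangle <- function(amp = 6, ttp = 0.3, dur = 1.0, fwhm = dur / 2,
                           fps = 1000) {
  w <- generate_pulse_waveform(waveform_spec(amp, ttp, dur, fwhm), fps)
  averaged_pulse(w, dt = 1 / fps, duration_s = dur)
}

test_that("the five parameters are exact on a closed-form triangle", {
  p <- dense_triangle()
  expect_equal(peak_amplitude(p), 6, tolerance = 1e-3)
  tt <- time_to_peak(p)
  expect_equal(tt$seconds, 0.3, tolerance = 1e-3)
  expect_equal(tt$pct_duration, 30, tolerance = 0.1)
  fw <- pulse_fwhm(p)
  expect_equal(fw$seconds, 0.5, tolerance = 2e-3)   # crossings at 0.15 / 0.65
  expect_equal(fw$pct_duration, 50, tolerance = 0.2)
  expect_equal(pulse_duration(p), 1.0)
  # all steepness estimators coincide on the linear rise: 0 -> 6 in 0.3 s
  for (v in c("rise_30_70", "min_max", "rise_47_53", "max_derivative"))
    expect_equal(pulse_steepness(p, v), 20, tolerance = 0.01)
})

test_that("extractors agree with the dense crossing-search oracle", {
  set.seed(202)
  fps <- 1000
  for (i in 1:100) {
    shape <- if (i %% 2 == 0) "triangle" else "smooth"
    dur <- runif(1, 0.7, 1.6)
    ttp <- runif(1, 0.15, 0.45) * dur
    fw <- if (shape == "triangle") {
      runif(1, max(ttp / 2, 0.25 * dur) + 0.02 * dur, dur / 2)
    } else {
      runif(1, 2 * ttp / 3 + 0.05 * dur,
            2 * ttp / 3 + (dur - ttp) - 0.05 * dur)
    }
    spec <- waveform_spec(runif(1, 2, 10), ttp, dur, fwhm = fw, shape = shape)
    w <- generate_pulse_waveform(spec, fps)
    pulse <- averaged_pulse(w, dt = 1 / fps, duration_s = dur)
    orc <- oracle_pulse_parameters(w, 1 / fps)
    expect_equal(peak_amplitude(pulse), orc$amplitude, tolerance = 1e-12)
    expect_lt(abs(time_to_peak(pulse)$seconds - orc$ttp), 0.002)
    expect_lt(abs(pulse_fwhm(pulse)$seconds - orc$fwhm), 0.002)
  }
})

test_that("parameters obey their scaling laws", {
  p <- dense_triangle(amp = 4, ttp = 0.25, dur = 1.2, fwhm = 0.55)
  # amplitude scaling scales amplitude and steepness, not timing
  p2 <- p; p2$values <- p$values * 2.5; p2$sd <- p$sd * 2.5
  expect_equal(peak_amplitude(p2), 2.5 * peak_amplitude(p))
  expect_equal(pulse_steepness(p2), 2.5 * pulse_steepness(p))
  expect_equal(time_to_peak(p2)$seconds, time_to_peak(p)$seconds)
  # time dilation halves steepness, doubles fwhm_s, keeps fwhm_pct
  p3 <- averaged_pulse(p$values, dt = 2 * p$dt, duration_s = 2 * p$duration_s)
  expect_equal(pulse_steepness(p3), pulse_steepness(p) / 2)
  expect_equal(pulse_fwhm(p3)$seconds, 2 * pulse_fwhm(p)$seconds)
  expect_equal(pulse_fwhm(p3)$pct_duration, pulse_fwhm(p)$pct_duration)
  expect_equal(time_to_peak(p3)$pct_duration, time_to_peak(p)$pct_duration)
  # symmetric pulse peaks at half its duration
  sym <- averaged_pulse(sin(pi * (0:100) / 100), dt = 0.01, duration_s = 1)
  expect_equal(time_to_peak(sym)$pct_duration, 50)
  # re-referencing after adding a constant changes nothing
  p4 <- p; p4$values <- (p$values + 3) - 3
  expect_equal(extract_pulse_parameters(p4), extract_pulse_parameters(p))
})

test_that("degenerate pulses raise informative errors", {
  flat <- averaged_pulse(rep(0, 50), dt = 0.04)
  expect_error(peak_amplitude(flat), "non-positive")
  neg <- averaged_pulse(c(0, -1, -2, -1, 0), dt = 0.04)
  expect_error(peak_amplitude(neg), "non-positive")
  first <- averaged_pulse(c(5, 4, 3, 2, 1, 0), dt = 0.04)
  expect_error(time_to_peak(first), "first sample")
  # pulse ending above half maximum: FWHM undefined
  rise_only <- averaged_pulse(seq(0, 6, length.out = 50), dt = 0.02)
  expect_error(pulse_fwhm(rise_only), "above half maximum")
})

test_that("duration reporting follows the beat arithmetic", {
  beat <- waveform_value(waveform_spec(5, 0.3, 1.0), (0:24) / 25)
  sig <- make_sig(c(rep(beat, 3), 0))
  expect_equal(pulse_duration(average_pulses(
    sig, pulse_labels(seq(1, 76, 25), fps = 25))), 1.0)
  b20 <- waveform_value(waveform_spec(5, 0.24, 0.8), (0:19) / 25)
  sig2 <- make_sig(c(rep(b20, 3), 0))
  expect_equal(pulse_duration(average_pulses(
    sig2, pulse_labels(seq(1, 61, 20), fps = 25))), 0.8)
})
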