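#' Pulse waveform parameter extraction
#'
#' The averaged pulse is summarized by five descriptors: peak amplitude (%A),
#' steepness of the ascending limb (%A/s), time-to-peak (s and % of
#' duration), full width at half maximum (s and % of duration), and pulse
#' duration (s). Crossings of fractional-amplitude levels are located by
#' linear interpolation between samples, so timing resolution is finer than
#' the sample period. Peak ties break to the earliest sample.
#'
#' @name pulse-parameters
NULL

.pulse_values <- function(pulse) {
  stopifnot(inherits(pulse, "averaged_pulse"))
  pulse$values
}

# first upward crossing of `level` in v[1..k_peak], interpolated; time in s
.cross_up <- function(v, dt, k_peak, level) {
  k <- which(v[seq_len(k_peak)] >= level)[1]
  if (is.na(k))
    stop(sprintf("ascending crossing of level %.4g not found before peak", level))
  if (k == 1L) return(0)
  (k - 2 + (level - v[k - 1]) / (v[k] - v[k - 1])) * dt
}

# first downward crossing of `level` after the peak, interpolated; time in s
.cross_down <- function(v, dt, k_peak, level) {
  idx <- seq(k_peak, length(v))
  k <- idx[which(v[idx] <= level)[1]]
  if (is.na(k))
    stop(sprintf(
      "descending crossing of level %.4g never reached: pulse ends above half maximum",
      level))
  if (k == k_peak) return((k_peak - 1) * dt)
  (k - 2 + (level - v[k - 1]) / (v[k] - v[k - 1])) * dt
}

#' Peak amplitude of an averaged pulse
#'
#' The maximum value of the re-referenced averaged pulse, in %A. Interpreted
#' as the maximum pulsatile blood-volume change relative to the start of the
#' cardiac cycle.
#'
#' @param pulse An [averaged_pulse] object.
#' @return Peak amplitude in %A.
#' @export
peak_amplitude <- function(pulse) {
  v <- .pulse_values(pulse)
  m <- max(v)
  if (!is.finite(m) || m <= 0)
    stop("peak_amplitude: invalid pulse (non-positive maximum)")
  m
}

#' Time-to-peak of an averaged pulse
#'
#' Time from the beat start to the waveform maximum (earliest maximal
#' sample), in seconds and as a percentage of pulse duration.
#'
#' @inheritParams peak_amplitude
#' @return List with `seconds` and `pct_duration`.
#' @export
time_to_peak <- function(pulse) {
  v <- .pulse_values(pulse)
  k <- which.max(v)
  if (k == 1L) stop("time_to_peak: peak at first sample; invalid pulse")
  tt <- (k - 1) * pulse$dt
  list(seconds = tt, pct_duration = 100 * tt / pulse$duration_s)
}

#' Full width at half maximum of an averaged pulse
#'
#' Width of the pulse at 50% of its peak amplitude: the interval between the
#' last-before-peak upward crossing and the first-after-peak downward
#' crossing of half maximum, each located by linear interpolation.
#'
#' @inheritParams peak_amplitude
#' @return List with `seconds` and `pct_duration`.
#' @export
pulse_fwhm <- function(pulse) {
  v <- .pulse_values(pulse)
  amp <- peak_amplitude(pulse)
  k <- which.max(v)
  t_up <- .cross_up(v, pulse$dt, k, amp / 2)
  t_dn <- .cross_down(v, pulse$dt, k, amp / 2)
  w <- t_dn - t_up
  list(seconds = w, pct_duration = 100 * w / pulse$duration_s)
}

#' Steepness of the ascending pulse limb
#'
#' Speed of blood-volume increase during systole, in %A/s. The default
#' estimator divides the rise from 30% to 70% of peak amplitude by the
#' elapsed time; alternates are the minimum-to-maximum slope
#' (`amplitude / time-to-peak`), the analogous 47-53% rise, and the maximum
#' of the central-difference derivative.
#'
#' @inheritParams peak_amplitude
#' @param variant One of `"rise_30_70"` (default), `"min_max"`,
#'   `"rise_47_53"`, `"max_derivative"`.
#' @return Steepness in %A/s.
#' @export
pulse_steepness <- function(pulse,
                            variant = c("rise_30_70", "min_max",
                                        "rise_47_53", "max_derivative")) {
  variant <- match.arg(variant)
  v <- .pulse_values(pulse)
  amp <- peak_amplitude(pulse)
  k <- which.max(v)
  dt <- pulse$dt
  switch(variant,
    rise_30_70 = {
      t30 <- .cross_up(v, dt, k, 0.30 * amp)
      t70 <- .cross_up(v, dt, k, 0.70 * amp)
      0.40 * amp / (t70 - t30)
    },
    rise_47_53 = {
      t47 <- .cross_up(v, dt, k, 0.47 * amp)
      t53 <- .cross_up(v, dt, k, 0.53 * amp)
      0.06 * amp / (t53 - t47)
    },
    min_max = amp / time_to_peak(pulse)$seconds,
    max_derivative = {
      n <- length(v)
      if (n < 3) stop("pulse_steepness: pulse too short for differentiation")
      max((v[3:n] - v[1:(n - 2)]) / (2 * dt))
    })
}

#' Duration of an averaged pulse
#'
#' The mean duration of the beats that contributed to the average, in
#' seconds (set when the averaged pulse is formed).
#'
#' @inheritParams peak_amplitude
#' @return Duration in seconds.
#' @export
pulse_duration <- function(pulse) {
  stopifnot(inherits(pulse, "averaged_pulse"))
  pulse$duration_s
}

#' Extract all five pulse parameters
#'
#' One-stop extraction of the waveform descriptor set from an averaged
#' pulse, returned as a one-row data frame matching the per-sequence
#' parameter table layout.
#'
#' @inheritParams pulse_steepness
#' @return A one-row `data.frame` with columns `peak_amplitude`, `steepness`,
#'   `ttp_s`, `ttp_pct`, `fwhm_s`, `fwhm_pct`, `duration_s`,
#'   `steepness_variant`, `n_pulses`.
#' @export
extract_pulse_parameters <- function(pulse,
                                     variant = c("rise_30_70", "min_max",
                                                 "rise_47_53",
                                                 "max_derivative")) {
  variant <- match.arg(variant)
  ttp <- time_to_peak(pulse)
  fw <- pulse_fwhm(pulse)
  data.frame(
    peak_amplitude = peak_amplitude(pulse),
    steepness = pulse_steepness(pulse, variant),
    ttp_s = ttp$seconds,
    ttp_pct = ttp$pct_duration,
    fwhm_s = fw$seconds,
    fwhm_pct = fw$pct_duration,
    duration_s = pulse_duration(pulse),
    steepness_variant = variant,
    n_pulses = pulse$n_pulses,
    stringsAsFactors = FALSE)
}
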