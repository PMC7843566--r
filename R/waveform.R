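#' Parametric cardiac pulse waveform specification
#'
#' Defines a single-beat absorption waveform by the descriptors that the
#' parameter-extraction stage measures: peak amplitude (%A), time-to-peak,
#' full width at half maximum and pulse duration. Two shape families are
#' supported:
#'
#' * `"triangle"`: piecewise-linear rise from 0 to `amplitude` over
#'   `time_to_peak`, then linear decay reaching 0 at `2 * fwhm` (the decay
#'   endpoint is fixed by the half-width geometry), flat 0 afterwards until
#'   `duration`. Analytically checkable: on the linear rise all steepness
#'   estimators coincide.
#' * `"smooth"`: sinusoidal rise `amplitude * sin(pi * t / (2 * time_to_peak))`
#'   on `[0, time_to_peak]` and a cosine-power decay
#'   `amplitude * cos(pi/2 * (t - ttp)/(duration - ttp))^q` afterwards. The
#'   exponent `q` is solved in closed form so the waveform attains the
#'   requested `fwhm`; the curve is continuously differentiable at the peak
#'   and reaches exactly 0 at `duration` (an asymmetric, gamma-variate-like
#'   fast-rise / slow-decay beat).
#'
#' Infeasible `(time_to_peak, fwhm, duration)` triples are rejected with an
#' error naming the violated constraint. When `fwhm` is `NULL` it defaults to
#' `duration / 2` (the value a symmetric-decay triangle attains).
#'
#' @param amplitude Peak amplitude in %A; must be > 0.
#' @param time_to_peak Time from pulse start to peak, seconds.
#' @param duration Total beat duration, seconds.
#' @param fwhm Full width at half maximum, seconds, or `NULL` for the default.
#' @param shape `"triangle"` or `"smooth"`.
#' @return An object of class `waveform_spec`.
#' @seealso [generate_pulse_waveform()], [waveform_value()]
#' @export
waveform_spec <- function(amplitude, time_to_peak, duration, fwhm = NULL,
                          shape = c("triangle", "smooth")) {
  shape <- match.arg(shape)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude <= 0)
    stop("waveform_spec: 'amplitude' must be > 0 (%A)")
  if (!(time_to_peak > 0 && time_to_peak < duration))
    stop("waveform_spec: need 0 < time_to_peak < duration")
  if (is.null(fwhm)) fwhm <- duration / 2
  if (!(fwhm > 0 && fwhm < duration))
    stop("waveform_spec: need 0 < fwhm < duration")
  if (shape == "triangle") {
    if (fwhm <= time_to_peak / 2)
      stop("waveform_spec: triangle family needs fwhm > time_to_peak / 2 ",
           "(half-rise crossing sits at time_to_peak / 2)")
    if (2 * fwhm > duration + 1e-12)
      stop("waveform_spec: triangle family needs 2 * fwhm <= duration ",
           "(decay reaches zero at 2 * fwhm)")
  } else {
    # half-rise sits at time_to_peak / 3 (sin limb), so the half-fall at
    # time_to_peak/3 + fwhm must land inside the decay interval
    lo <- 2 * time_to_peak / 3
    hi <- 2 * time_to_peak / 3 + (duration - time_to_peak)
    if (fwhm <= lo || fwhm >= hi)
      stop(sprintf(paste0("waveform_spec: smooth family needs ",
                          "2*time_to_peak/3 < fwhm < 2*time_to_peak/3 + ",
                          "(duration - time_to_peak); feasible range ",
                          "(%.4g, %.4g)"), lo, hi))
  }
  structure(list(amplitude = amplitude, time_to_peak = time_to_peak,
                 fwhm = fwhm, duration = duration, shape = shape),
            class = "waveform_spec")
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf(
    "waveform_spec [%s]: amplitude %.3g %%A, time-to-peak %.3g s, FWHM %.3g s, duration %.3g s\n",
    x$shape, x$amplitude, x$time_to_peak, x$fwhm, x$duration))
  invisible(x)
}

# exponent of the cosine-power decay that yields the requested fwhm:
# the half-fall crossing lies at ttp/3 + fwhm, i.e. fwhm - 2*ttp/3 into
# the decay interval
.smooth_decay_exponent <- function(spec) {
  theta <- (spec$fwhm - 2 * spec$time_to_peak / 3) * pi /
    (2 * (spec$duration - spec$time_to_peak))
  log(0.5) / log(cos(theta))
}

#' Evaluate a pulse waveform at arbitrary times
#'
#' Continuous-time evaluation of the parametric beat; times outside
#' `[0, duration]` evaluate to 0, as do times past the triangle family's
#' decay endpoint.
#'
#' @param spec A [waveform_spec()].
#' @param t Numeric vector of times in seconds.
#' @return Numeric vector of absorption values in %A.
#' @export
waveform_value <- function(spec, t) {
  stopifnot(inherits(spec, "waveform_spec"))
  a <- spec$amplitude; ttp <- spec$time_to_peak
  v <- numeric(length(t))
  if (spec$shape == "triangle") {
    t_end <- 2 * spec$fwhm
    r <- t >= 0 & t <= ttp
    f <- t > ttp & t < t_end
    v[r] <- a * t[r] / ttp
    v[f] <- a * (1 - (t[f] - ttp) / (t_end - ttp))
  } else {
    q <- .smooth_decay_exponent(spec)
    r <- t >= 0 & t <= ttp
    f <- t > ttp & t < spec$duration
    v[r] <- a * sin(pi * t[r] / (2 * ttp))
    v[f] <- a * cos(pi / 2 * (t[f] - ttp) / (spec$duration - ttp))^q
  }
  v
}

#' Sample a pulse waveform at a fixed frame rate
#'
#' Produces one absorption value per frame interval, `round(duration * fps)`
#' samples at times `(k - 1) / fps`. The sampled maximum approaches
#' `amplitude` as `fps` grows; at any rate the peak sample falls within one
#' sample period of `time_to_peak`.
#'
#' @param spec A [waveform_spec()].
#' @param fps Sampling rate, frames per second (> 0).
#' @return Numeric vector of %A values with attribute `"fps"`.
#' @export
generate_pulse_waveform <- function(spec, fps) {
  stopifnot(inherits(spec, "waveform_spec"))
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("generate_pulse_waveform: fps must be > 0")
  n <- round(spec$duration * fps)
  if (n < 2) stop("generate_pulse_waveform: duration * fps < 2 samples")
  w <- waveform_value(spec, (seq_len(n) - 1) / fps)
  attr(w, "fps") <- fps
  w
}
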