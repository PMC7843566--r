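#' Pulse label set
#'
#' Ordered frame indices (1-based) of the local minima that delimit selected
#' pulses: `k` labels define `k - 1` beats. Labels come from manual
#' inspection of the plethysmographic trace (the primary, artifact-safe
#' path) or from automated screening. Label files carry no diagnosis field,
#' so whoever labels is necessarily masked to any grouping.
#'
#' @param minima_frames Strictly increasing integer frame indices (>= 2).
#' @param fps Frames per second, used to validate beat durations.
#' @param source `"manual"` or `"auto"`.
#' @param min_period_s,max_period_s Plausible beat-period bounds in seconds
#'   (defaults 0.33 and 2.0, i.e. 30-180 beats/min). Adjacent labels
#'   closer than `min_period_s` are rejected; a gap longer than
#'   `max_period_s` is allowed but delimits no beat (it marks a skipped,
#'   distorted stretch), so at least one adjacent pair must fall inside
#'   the plausible range.
#' @return An object of class `pulse_labels`.
#' @export
pulse_labels <- function(minima_frames, fps, source = c("manual", "auto"),
                         min_period_s = 0.33, max_period_s = 2.0) {
  source <- match.arg(source)
  m <- as.integer(minima_frames)
  if (length(m) < 2L)
    stop("pulse_labels: need >= 2 labelled minima (>= 1 pulse)")
  if (any(diff(m) <= 0))
    stop("pulse_labels: minima_frames must be strictly increasing")
  gaps <- diff(m) / fps
  if (any(gaps < min_period_s))
    stop(sprintf(
      "pulse_labels: adjacent labels only %.2f s apart (< %.2f s minimum beat period)",
      min(gaps), min_period_s))
  if (!any(gaps <= max_period_s))
    stop(sprintf(
      "pulse_labels: no adjacent pair within %.2f s; no beat can be formed",
      max_period_s))
  structure(list(minima_frames = m, fps = fps, source = source,
                 min_period_s = min_period_s, max_period_s = max_period_s),
            class = "pulse_labels")
}

# index pairs (start, end) of labelled beats: adjacent minima whose gap is
# a plausible beat period; an explicit beat table (set by select_pulses
# when it drops an interior beat) takes precedence
.label_beats <- function(labels) {
  if (!is.null(labels$beats)) return(labels$beats)
  m <- labels$minima_frames
  gaps <- diff(m) / labels$fps
  ok <- gaps >= labels$min_period_s & gaps <= labels$max_period_s
  cbind(start = m[-length(m)][ok], end = m[-1][ok])
}

#' Read / write pulse label JSON files
#'
#' Schema: `{"sequence_id": str, "fps": num, "minima_frames": [int,...],
#' "source": "manual"|"auto"}`. Frame indices are stored 1-based. A label
#' file containing a diagnosis/group field is rejected so that pulse
#' selection stays masked to the diagnosis.
#'
#' @param path File path.
#' @param labels A [pulse_labels] object.
#' @param sequence_id Identifier stored alongside the labels.
#' @return `read_pulse_labels` returns a [pulse_labels] object with
#'   attribute `"sequence_id"`; `write_pulse_labels` returns `path`
#'   invisibly.
#' @export
read_pulse_labels <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  banned <- intersect(names(x), c("group", "diagnosis"))
  if (length(banned))
    stop("read_pulse_labels: label files must not carry a diagnosis field (",
         paste(banned, collapse = ", "), ")")
  lab <- pulse_labels(x$minima_frames, fps = x$fps, source = x$source)
  attr(lab, "sequence_id") <- x$sequence_id
  lab
}

#' @rdname read_pulse_labels
#' @export
write_pulse_labels <- function(labels, path, sequence_id = "seq") {
  stopifnot(inherits(labels, "pulse_labels"))
  jsonlite::write_json(
    list(sequence_id = sequence_id, fps = labels$fps,
         minima_frames = labels$minima_frames, source = labels$source),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Detect candidate pulse minima in a plethysmographic signal
#'
#' Local minima of the %A trace, screened by a minimum temporal separation
#' and by prominence (trough depth relative to the lower of the two
#' enclosing maxima) of at least `min_prominence_frac` of the median trough
#' prominence. Minima within `flag_margin` frames of a flagged (blink/blur)
#' frame are discarded, because a distorted trough cannot anchor a beat.
#'
#' @param sig A [pleth_signal] object.
#' @param min_separation_s Minimum distance between minima, seconds.
#' @param min_prominence_frac Fraction of the median prominence below which
#'   a trough is dropped.
#' @param flag_margin Frames of clearance required around flagged frames.
#' @return Integer vector of frame indices (possibly empty).
#' @export
detect_minima <- function(sig, min_separation_s = 0.33,
                          min_prominence_frac = 0.3, flag_margin = 2L) {
  stopifnot(inherits(sig, "pleth_signal"))
  a <- sig$a_pct
  n <- length(a)
  if (n < sig$fps) stop("detect_minima: need >= 1 s of signal")
  interior <- 2:(n - 1)
  cand <- interior[a[interior] <= a[interior - 1] & a[interior] <= a[interior + 1]]
  # collapse plateaus: keep first sample of runs of equal neighbours
  if (length(cand) > 1L) cand <- cand[c(TRUE, diff(cand) > 1L)]
  if (!length(cand)) return(integer(0))
  # enforce separation, keeping deeper minima first
  min_sep <- round(min_separation_s * sig$fps)
  keep <- logical(length(cand))
  for (i in order(a[cand])) {
    if (!any(keep & abs(cand - cand[i]) < min_sep)) keep[i] <- TRUE
  }
  cand <- sort(cand[keep])
  prom <- vapply(seq_along(cand), function(i) {
    lo <- if (i == 1L) 1L else cand[i - 1L]
    hi <- if (i == length(cand)) n else cand[i + 1L]
    min(max(a[lo:cand[i]]), max(a[cand[i]:hi])) - a[cand[i]]
  }, numeric(1))
  cand <- cand[prom > 1e-12 &
                 prom >= min_prominence_frac * stats::median(prom)]
  flagged <- which(sig$frame_flags != "ok")
  if (length(flagged) && length(cand)) {
    near <- vapply(cand, function(k) any(abs(flagged - k) <= flag_margin),
                   logical(1))
    cand <- cand[!near]
  }
  cand
}

#' Select reliable pulses
#'
#' Manual labels (the primary, artifact-safe path) pass through after
#' validation.
#' In automatic mode, a beat delimited by consecutive minima is kept only
#' if (a) it contains no flagged frame, (b) its duration lies within
#' `duration_tol` of the median beat duration, and (c) its peak amplitude
#' lies within `amplitude_tol` of the median beat amplitude. At least
#' `min_pulses` beats must survive.
#'
#' @param minima Integer frame indices from [detect_minima()].
#' @param sig A [pleth_signal].
#' @param labels Optional manual [pulse_labels]; if supplied they are
#'   validated and returned unchanged.
#' @param duration_tol,amplitude_tol Relative tolerances around the medians
#'   (defaults 0.25 and 0.50).
#' @param min_pulses Minimum number of surviving beats (default 2, the
#'   smallest count used in practice).
#' @param max_pulses Maximum beats retained (default 7); when more
#'   survive, the ones closest to the median duration are kept.
#' @return A [pulse_labels] object (`source = "auto"` unless manual).
#' @export
select_pulses <- function(minima, sig, labels = NULL,
                          duration_tol = 0.25, amplitude_tol = 0.50,
                          min_pulses = 2L, max_pulses = 7L) {
  stopifnot(inherits(sig, "pleth_signal"))
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "pulse_labels"))
    if (max(labels$minima_frames) > length(sig$a_pct))
      stop("select_pulses: manual labels exceed signal length")
    return(labels)
  }
  if (length(minima) < 2L)
    stop("select_pulses: fewer than 2 candidate minima; no pulse can be formed")
  starts <- minima[-length(minima)]
  ends <- minima[-1]
  durs <- (ends - starts) / sig$fps
  amps <- mapply(function(s, e) {
    seg <- sig$a_pct[s:e]
    max(seg) - seg[1]
  }, starts, ends)
  has_flag <- mapply(function(s, e) any(sig$frame_flags[s:e] != "ok"),
                     starts, ends)
  med_d <- stats::median(durs)
  med_a <- stats::median(amps)
  reasons <- character(length(starts))
  reasons[has_flag] <- "flagged frame"
  bad_p <- !has_flag & (durs < 0.33 | durs > 2.0)
  reasons[bad_p] <- "implausible beat period"
  bad_d <- reasons == "" & abs(durs - med_d) > duration_tol * med_d
  reasons[bad_d] <- "duration outside median +/- 25%"
  bad_a <- reasons == "" & abs(amps - med_a) > amplitude_tol * med_a
  reasons[bad_a] <- "amplitude outside median +/- 50%"
  ok <- reasons == ""
  if (sum(ok) < min_pulses) {
    rej <- paste(sprintf("pulse %d (frames %d-%d): %s",
                         which(!ok), starts[!ok], ends[!ok], reasons[!ok]),
                 collapse = "; ")
    stop("select_pulses: fewer than ", min_pulses,
         " reliable pulses survive screening. Rejected: ", rej)
  }
  keep <- which(ok)
  if (length(keep) > max_pulses)
    keep <- sort(keep[order(abs(durs[keep] - med_d))][seq_len(max_pulses)])
  out <- pulse_labels(sort(unique(c(starts[keep], ends[keep]))),
                      fps = sig$fps, source = "auto")
  out$beats <- cbind(start = starts[keep], end = ends[keep])
  attr(out, "rejected") <- data.frame(start = starts[!ok], end = ends[!ok],
                                      reason = reasons[!ok])
  out
}

#' Construct an averaged-pulse object
#'
#' @param values Per-sample %A values, starting at 0 (re-referenced).
#' @param sd Per-sample standard deviation across contributing beats.
#' @param dt Sample spacing in seconds.
#' @param duration_s Pulse duration in seconds (mean of contributing beats).
#' @param n_pulses Number of beats averaged.
#' @param fps Frame rate of the source video.
#' @return Object of class `averaged_pulse`.
#' @export
averaged_pulse <- function(values, sd = rep(0, length(values)), dt,
                           duration_s = dt * (length(values) - 1),
                           n_pulses = 1L, fps = 1 / dt) {
  stopifnot(length(values) == length(sd), dt > 0, duration_s > 0)
  structure(list(values = as.numeric(values), sd = as.numeric(sd), dt = dt,
                 duration_s = duration_s, n_pulses = as.integer(n_pulses),
                 fps = fps),
            class = "averaged_pulse")
}

#' @export
print.averaged_pulse <- function(x, ...) {
  cat(sprintf(
    "averaged_pulse: %d beats, duration %.3f s, %d samples (dt %.4f s), peak %.3g %%A\n",
    x$n_pulses, x$duration_s, length(x$values), x$dt, max(x$values)))
  invisible(x)
}

#' @export
plot.averaged_pulse <- function(x, ...) {
  t <- (seq_along(x$values) - 1) * x$dt
  graphics::plot(t, x$values, type = "n", xlab = "time (s)",
                 ylab = "absorption (%A)",
                 main = sprintf("Averaged pulse (n = %d)", x$n_pulses), ...)
  graphics::polygon(c(t, rev(t)),
                    c(x$values + x$sd, rev(x$values - x$sd)),
                    col = grDevices::adjustcolor("red", 0.25), border = NA)
  graphics::lines(t, x$values, col = "red", lwd = 2)
  invisible(x)
}

#' Average the selected pulses of a plethysmographic signal
#'
#' Each beat spans the samples from one labelled minimum to the next
#' (inclusive). Beats are re-referenced by subtracting their first sample
#' (the heartbeat starting point is the reference value), linearly resampled
#' to a common grid of `round(median beat length)` intervals, and averaged
#' sample-wise; the per-sample SD across beats is retained. The reported
#' duration is the mean of the individual beat durations.
#'
#' @param sig A [pleth_signal].
#' @param labels A [pulse_labels] object.
#' @param min_pulses Minimum beats required (default 2; set to 1 to allow a
#'   single-beat "average" with zero SD).
#' @return An [averaged_pulse].
#' @export
average_pulses <- function(sig, labels, min_pulses = 2L) {
  stopifnot(inherits(sig, "pleth_signal"), inherits(labels, "pulse_labels"))
  bt <- .label_beats(labels)
  n_beats <- nrow(bt)
  if (n_beats < min_pulses)
    stop("average_pulses: ", n_beats, " beat(s) labelled; need >= ", min_pulses)
  if (max(bt) > length(sig$a_pct))
    stop("average_pulses: labels exceed signal length")
  lens <- bt[, "end"] - bt[, "start"]   # beat lengths in frame intervals
  L <- round(stats::median(lens))
  grid <- seq(0, 1, length.out = L + 1L)
  beats <- vapply(seq_len(n_beats), function(i) {
    seg <- sig$a_pct[bt[i, "start"]:bt[i, "end"]]
    seg <- seg - seg[1]
    stats::approx(seq(0, 1, length.out = length(seg)), seg, xout = grid)$y
  }, numeric(L + 1L))
  beats <- matrix(beats, nrow = L + 1L)
  duration_s <- mean(lens) / sig$fps
  if (n_beats == 1L)
    warning("average_pulses: single beat; SD is zero by construction")
  sd_vec <- if (n_beats == 1L) rep(0, L + 1L) else apply(beats, 1, stats::sd)
  averaged_pulse(values = rowMeans(beats),
                 sd = sd_vec,
                 dt = duration_s / L,
                 duration_s = duration_s,
                 n_pulses = n_beats,
                 fps = sig$fps)
}

#' Pulse rate from labelled minima
#'
#' @param labels A [pulse_labels] object.
#' @param fps Frames per second (defaults to the label set's fps).
#' @return Pulse rate in beats per minute: `60 /` mean beat interval in
#'   seconds (plausible-gap adjacent label pairs only).
#' @export
pulse_rate <- function(labels, fps = labels$fps) {
  stopifnot(inherits(labels, "pulse_labels"))
  bt <- .label_beats(labels)
  60 / (mean(bt[, "end"] - bt[, "start"]) / fps)
}
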