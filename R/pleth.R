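#' Plethysmographic signal container
#'
#' Per-frame traces of the ROI-mean grey level `i_raw`, its slowly varying
#' trend `i_trend`, and the trend-corrected absorption signal
#' `a_pct = (1 - i_raw / i_trend) * 100` in %A. Higher blood volume
#' absorbs more light, lowers the reflected intensity, and raises `a_pct`.
#' `display_100 = 100 + a_pct` is the display convention in which the
#' signal reads as a relative deviation of absorption from its average
#' value 100 (105 means 5% more absorption).
#'
#' @param i_raw,i_trend,a_pct,display_100 Equal-length numeric traces.
#' @param fps Frames per second.
#' @param frame_flags Per-frame quality flags.
#' @return Object of class `pleth_signal`.
#' @export
pleth_signal <- function(i_raw, i_trend, a_pct, display_100, fps,
                         frame_flags = rep("ok", length(i_raw))) {
  n <- length(i_raw)
  if (length(i_trend) != n || length(a_pct) != n || length(display_100) != n)
    stop("pleth_signal: all traces must have equal length")
  if (any(!is.na(i_trend) & i_trend <= 0))
    stop("pleth_signal: i_trend must be strictly positive")
  if (length(frame_flags) != n)
    stop("pleth_signal: one flag per frame required")
  structure(list(i_raw = i_raw, i_trend = i_trend, a_pct = a_pct,
                 display_100 = display_100, fps = fps,
                 frame_flags = frame_flags),
            class = "pleth_signal")
}

#' @export
print.pleth_signal <- function(x, ...) {
  cat(sprintf(
    "pleth_signal: %d frames at %g fps; a_pct range [%.2f, %.2f] %%A; %d flagged\n",
    length(x$a_pct), x$fps, min(x$a_pct, na.rm = TRUE),
    max(x$a_pct, na.rm = TRUE), sum(x$frame_flags != "ok")))
  invisible(x)
}

#' @export
plot.pleth_signal <- function(x, ...) {
  t <- (seq_along(x$i_raw) - 1) / x$fps
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(t, x$i_raw, type = "l", col = "blue", lwd = 2,
                 xlab = "time (s)", ylab = "grey level",
                 main = "raw ROI intensity and trend", ...)
  graphics::lines(t, x$i_trend, col = "red")
  graphics::plot(t, x$a_pct, type = "l", lty = 3, xlab = "time (s)",
                 ylab = "absorption (%A)", main = "trend-corrected signal")
  invisible(x)
}

#' Extract the ROI-mean intensity trace from a registered video
#'
#' For each frame, the mean grey level over the tissue-ROI pixels that are
#' still in the field of view. A frame whose ROI left the field entirely
#' gets `NA` and is flagged `edge_loss`.
#'
#' @param video A registered [video_sequence].
#' @param roi A non-empty [roi_mask] (normally the `onh_tissue_roi`).
#' @return Numeric vector `i_raw` with attribute `"flags"` (the possibly
#'   updated per-frame flags).
#' @export
extract_intensity_signal <- function(video, roi) {
  stopifnot(inherits(video, "video_sequence"), inherits(roi, "roi_mask"))
  if (!any(roi$mask)) stop("extract_intensity_signal: empty ROI")
  if (!identical(dim(roi$mask), dim(video$frames)[1:2]))
    stop("extract_intensity_signal: ROI shape does not match frames")
  n <- n_frames(video)
  idx <- which(roi$mask)
  flags <- video$flags
  i_raw <- vapply(seq_len(n), function(i) {
    f <- video$frames[, , i]
    v <- if (is.null(video$valid)) rep(TRUE, length(idx)) else
      video$valid[, , i][idx]
    if (!any(v)) return(NA_real_)
    mean(f[idx][v])
  }, numeric(1))
  flags[is.na(i_raw) & flags == "ok"] <- "edge_loss"
  attr(i_raw, "flags") <- flags
  i_raw
}

#' Estimate the slowly varying intensity trend
#'
#' Centred moving average over a window of `round(window_s * fps)` frames
#' (forced odd), reflect-padded at the sequence edges. Flagged or missing
#' frames are excluded from each window's mean so a blink does not drag
#' the trend. The window must be at least one plausible pulse period so
#' that the cardiac modulation itself is not tracked.
#'
#' @param i_raw Raw intensity trace (NAs allowed at flagged frames).
#' @param fps Frames per second.
#' @param window_s Window length in seconds (default 1.5).
#' @param flags Optional per-frame flags; non-`ok` frames are excluded
#'   from the windows (defaults to the `"flags"` attribute of `i_raw`).
#' @return Numeric trend trace `i_trend`, strictly positive.
#' @export
estimate_trend <- function(i_raw, fps, window_s = 1.5, flags = NULL) {
  n <- length(i_raw)
  if (is.null(flags)) flags <- attr(i_raw, "flags")
  if (is.null(flags)) flags <- rep("ok", n)
  w <- round(window_s * fps)
  if (w %% 2 == 0) w <- w + 1L
  if (n < w) stop("estimate_trend: signal shorter than the trend window")
  use <- flags == "ok" & !is.na(i_raw)
  if (!any(use)) stop("estimate_trend: all frames flagged or missing")
  x <- ifelse(use, i_raw, 0)
  u <- as.numeric(use)
  # reflect-pad both series, then boxcar via filter
  h <- (w - 1) / 2
  pad <- function(z) c(z[(h + 1):2], z, z[(n - 1):(n - h)])
  box <- rep(1, w)
  num <- stats::filter(pad(x), box, sides = 2)[(h + 1):(h + n)]
  den <- stats::filter(pad(u), box, sides = 2)[(h + 1):(h + n)]
  if (any(den == 0))
    stop("estimate_trend: a window contains no usable frames")
  tr <- as.numeric(num / den)
  if (any(tr <= 0))
    stop("estimate_trend: non-positive trend (pathological input)")
  tr
}

#' Compute the trend-corrected plethysmographic signal
#'
#' `a_pct = (1 - i_raw / i_trend) * 100` (%A), plus the 100-referenced
#' display trace `display_100 = 100 + a_pct`: an intensity ratio
#' `i_raw / i_trend` of 0.95 reads as display value 105, i.e. a 5%
#' increase of absorption over the running average.
#'
#' @param i_raw,i_trend Equal-length traces; `i_trend > 0`.
#' @param fps Frames per second stored in the result.
#' @param flags Optional per-frame flags (defaults to the `"flags"`
#'   attribute of `i_raw`).
#' @return A [pleth_signal].
#' @export
compute_pleth_signal <- function(i_raw, i_trend, fps = 25, flags = NULL) {
  if (length(i_raw) != length(i_trend))
    stop("compute_pleth_signal: traces must have equal length")
  if (any(!is.na(i_trend) & i_trend <= 0))
    stop("compute_pleth_signal: i_trend must be strictly positive")
  if (is.null(flags)) flags <- attr(i_raw, "flags")
  if (is.null(flags)) flags <- rep("ok", length(i_raw))
  a <- (1 - as.numeric(i_raw) / as.numeric(i_trend)) * 100
  pleth_signal(i_raw = as.numeric(i_raw), i_trend = as.numeric(i_trend),
               a_pct = a, display_100 = 100 + a, fps = fps,
               frame_flags = flags)
}

#' Write a plethysmographic signal as CSV
#'
#' Columns: `frame,time_s,i_raw,i_trend,a_pct,flag`.
#'
#' @param sig A [pleth_signal].
#' @param path Output path.
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "pleth_signal"))
  n <- length(sig$i_raw)
  utils::write.csv(
    data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / sig$fps,
               i_raw = sig$i_raw, i_trend = sig$i_trend, a_pct = sig$a_pct,
               flag = sig$frame_flags),
    path, row.names = FALSE)
  invisible(path)
}
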