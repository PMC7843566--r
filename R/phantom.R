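#' Synthetic fundus scene phantom
#'
#' Geometric description of a phantom retina: a bright ONH disc carrying a
#' darker vessel tree on a more strongly absorbing (darker) surround, with
#' an optional smooth multiplicative texture. Grey levels follow a
#' multiplicative absorption model, `background_level * (1 - absorption)`,
#' which is exactly the model the trend-corrected signal definition
#' `A = 1 - I / I_avg` inverts.
#'
#' @param frame_shape Integer `(rows, cols)` in pixels.
#' @param onh_center `(row, col)` of the disc centre.
#' @param onh_radius Disc radius in pixels; the disc must lie fully inside
#'   the frame.
#' @param vessel_tree List of segments, each
#'   `list(from = c(r, c), to = c(r, c), width = px)`; `NULL` for the
#'   default 3-branch tree, `list()` for a vessel-free phantom.
#' @param background_level Full-scale grey level of an absorption-free
#'   pixel (default 220).
#' @param surround_absorption Static absorption of the surround outside
#'   the disc, in `[0, 1)`.
#' @param vessel_absorption Static absorption of vessel pixels, in
#'   `[0, 1)`.
#' @param tissue_absorption_gain Fraction of the pulse waveform's
#'   amplitude expressed by ONH tissue pixels (1 = full).
#' @param texture_amp Amplitude of the smooth static texture as a
#'   fraction of local grey level (default 0.03).
#' @return Object of class `scene_phantom`.
#' @export
scene_phantom <- function(frame_shape = c(100L, 100L),
                          onh_center = round(frame_shape / 2),
                          onh_radius = 30,
                          vessel_tree = NULL,
                          background_level = 220,
                          surround_absorption = 0.35,
                          vessel_absorption = 0.55,
                          tissue_absorption_gain = 1.0,
                          texture_amp = 0.03) {
  frame_shape <- as.integer(frame_shape)
  if (onh_center[1] - onh_radius < 1 || onh_center[1] + onh_radius > frame_shape[1] ||
      onh_center[2] - onh_radius < 1 || onh_center[2] + onh_radius > frame_shape[2])
    stop("scene_phantom: ONH disc must lie fully inside the frame")
  for (a in c(surround_absorption, vessel_absorption))
    if (a < 0 || a >= 1) stop("scene_phantom: absorption fractions must be in [0, 1)")
  if (tissue_absorption_gain < 0 || tissue_absorption_gain > 1)
    stop("scene_phantom: tissue_absorption_gain must be in [0, 1]")
  if (is.null(vessel_tree))
    vessel_tree <- default_vessel_tree(frame_shape, onh_center, onh_radius)
  for (seg in vessel_tree)
    if (seg$width < 1) stop("scene_phantom: vessel widths must be >= 1 px")
  structure(list(frame_shape = frame_shape, onh_center = onh_center,
                 onh_radius = onh_radius, vessel_tree = vessel_tree,
                 background_level = background_level,
                 surround_absorption = surround_absorption,
                 vessel_absorption = vessel_absorption,
                 tissue_absorption_gain = tissue_absorption_gain,
                 texture_amp = texture_amp),
            class = "scene_phantom")
}

#' Default phantom vessel tree
#'
#' Three straight vessel branches crossing the disc, 3 px wide, the
#' typical calibre of large ONH vessels at this field of view.
#'
#' @inheritParams scene_phantom
#' @return List of vessel segments.
#' @export
default_vessel_tree <- function(frame_shape, onh_center, onh_radius) {
  r0 <- onh_center[1]; c0 <- onh_center[2]
  L <- min(frame_shape) / 2 - 2
  list(
    list(from = c(r0 - L, c0 - L * 0.6), to = c(r0 + L, c0 + L * 0.6), width = 3),
    list(from = c(r0 - L, c0 + L * 0.5), to = c(r0 + L, c0 - L * 0.3), width = 3),
    list(from = c(r0, c0 - L), to = c(r0 + L * 0.2, c0 + L), width = 2))
}

# static scene maps: list(absorption, tissue, vessels, disc) matrices
.scene_maps <- function(phantom) {
  d <- phantom$frame_shape
  rr <- row(matrix(0, d[1], d[2])); cc <- col(matrix(0, d[1], d[2]))
  disc <- sqrt((rr - phantom$onh_center[1])^2 +
               (cc - phantom$onh_center[2])^2) <= phantom$onh_radius
  vessels <- matrix(FALSE, d[1], d[2])
  for (seg in phantom$vessel_tree) {
    a <- seg$from; b <- seg$to
    ab <- b - a
    len2 <- sum(ab^2)
    t_par <- pmin(pmax(((rr - a[1]) * ab[1] + (cc - a[2]) * ab[2]) / len2, 0), 1)
    dist <- sqrt((rr - (a[1] + t_par * ab[1]))^2 +
                 (cc - (a[2] + t_par * ab[2]))^2)
    vessels <- vessels | dist <= seg$width / 2
  }
  absorption <- matrix(0, d[1], d[2])
  absorption[!disc] <- phantom$surround_absorption
  absorption[vessels] <- phantom$vessel_absorption
  list(absorption = absorption, tissue = disc & !vessels,
       vessels = vessels, disc = disc)
}

#' Motion and artifact specification for a phantom video
#'
#' @param dx,dy Per-frame rigid translation in px (recycled to `n`).
#' @param theta Per-frame rotation in degrees.
#' @param n Number of frames (defaults to the longest trace given).
#' @param blink_frames,blur_frames Frame indices rendered as eyelid
#'   reflection (near-saturated) or motion/defocus blur.
#' @param noise_sd Gaussian sensor noise SD in grey levels.
#' @param seed Integer seed making the rendering reproducible.
#' @return Object of class `motion_artifact_spec`.
#' @export
motion_artifact_spec <- function(dx = 0, dy = 0, theta = 0, n = NULL,
                                 blink_frames = integer(0),
                                 blur_frames = integer(0),
                                 noise_sd = 0, seed = 1L) {
  if (is.null(n)) n <- max(length(dx), length(dy), length(theta))
  dx <- rep_len(dx, n); dy <- rep_len(dy, n); theta <- rep_len(theta, n)
  if (length(blink_frames) && (min(blink_frames) < 1 || max(blink_frames) > n))
    stop("motion_artifact_spec: blink_frames outside 1..n")
  if (length(blur_frames) && (min(blur_frames) < 1 || max(blur_frames) > n))
    stop("motion_artifact_spec: blur_frames outside 1..n")
  structure(list(dx = dx, dy = dy, theta = theta, n = n,
                 blink_frames = as.integer(blink_frames),
                 blur_frames = as.integer(blur_frames),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "motion_artifact_spec")
}

#' Sinusoidal drift motion trace
#'
#' Convenience builder for slow sinusoidal eye drift of a given amplitude.
#'
#' @param n Number of frames.
#' @param fps Frames per second.
#' @param amplitude_px Drift amplitude in pixels.
#' @param period_s Drift period in seconds.
#' @param phase Phase offset in radians.
#' @return Numeric vector of length `n`.
#' @export
sinusoidal_drift <- function(n, fps = 25, amplitude_px = 4, period_s = 3.1,
                             phase = 0) {
  amplitude_px * sin(2 * pi * (seq_len(n) - 1) / (fps * period_s) + phase)
}

#' Render a phantom fundus video with a known injected pulse
#'
#' Forward model, per frame `n` and pixel `p`:
#' `background_level * (1 - absorption(p)) * (1 - gain(p) * a(n) / 100)`,
#' where `a(n)` is the waveform in %A and `gain(p)` equals
#' `tissue_absorption_gain` on ONH tissue pixels and 0 elsewhere; the
#' static texture multiplies the scene; the frame is then rigidly moved,
#' blink frames are overwritten with a near-saturated level, blur frames
#' are Gaussian-blurred, and seeded sensor noise is added. The returned
#' ground truth makes every downstream stage testable.
#'
#' @param phantom A [scene_phantom].
#' @param waveform Numeric vector of %A values, one per frame (e.g. a
#'   tiled [generate_pulse_waveform()] output).
#' @param art A [motion_artifact_spec] whose length matches the waveform.
#' @return List with `video` (a [video_sequence], flags all `ok`:
#'   artifact detection is the pipeline's job) and `truth` (list:
#'   `motion` data frame, `waveform`, `roi` tissue [roi_mask], `vessels`
#'   mask, `onh` mask, `scene` absorption map).
#' @export
render_video <- function(phantom, waveform, art) {
  stopifnot(inherits(phantom, "scene_phantom"),
            inherits(art, "motion_artifact_spec"))
  n <- length(waveform)
  if (n != art$n)
    stop("render_video: waveform length (", n,
         ") and motion trace length (", art$n, ") differ")
  maps <- .scene_maps(phantom)
  d <- phantom$frame_shape
  set.seed(art$seed)
  texture <- if (phantom$texture_amp > 0) {
    1 + phantom$texture_amp *
      as.matrix(EBImage::gblur(matrix(stats::rnorm(prod(d)), d[1], d[2]), 6)) * 6
  } else matrix(1, d[1], d[2])
  static <- phantom$background_level * (1 - maps$absorption) * texture
  gain <- maps$tissue * phantom$tissue_absorption_gain
  frames <- array(0, c(d, n))
  for (i in seq_len(n)) {
    f <- static * (1 - gain * waveform[i] / 100)
    if (art$dx[i] != 0 || art$dy[i] != 0 || art$theta[i] != 0) {
      w <- apply_rigid(f, art$dx[i], art$dy[i], art$theta[i])
      # out-of-field pixels take the surround grey level, as if the scene
      # continued beyond the frame
      w[!attr(w, "valid")] <-
        phantom$background_level * (1 - phantom$surround_absorption)
      f <- w
    }
    if (i %in% art$blink_frames) {
      f <- matrix(0.96 * 255, d[1], d[2])
    } else if (i %in% art$blur_frames) {
      f <- as.matrix(EBImage::gblur(f, 5))
    }
    if (art$noise_sd > 0)
      f <- f + matrix(stats::rnorm(prod(d), 0, art$noise_sd), d[1], d[2])
    frames[, , i] <- f
  }
  truth <- list(
    motion = data.frame(frame = seq_len(n), dx = art$dx, dy = art$dy,
                        theta = art$theta),
    waveform = waveform,
    roi = roi_mask(maps$tissue, kind = "onh_tissue_roi", provenance = "manual"),
    onh = roi_mask(maps$disc, kind = "onh", provenance = "manual"),
    vessels = roi_mask(maps$vessels, kind = "vessels", provenance = "manual"),
    scene = maps$absorption)
  list(video = video_sequence(frames, fps = 25), truth = truth)
}

#' Tile a single-beat waveform over a frame count
#'
#' Repeats the sampled beat end to end and truncates to `n_frames`,
#' producing the periodic pulse train a steady heart would inject.
#'
#' @param beat Output of [generate_pulse_waveform()].
#' @param n_frames Total frames required.
#' @return Numeric vector of length `n_frames`.
#' @export
tile_waveform <- function(beat, n_frames) {
  rep_len(as.numeric(beat), n_frames)
}

#' Write phantom ground truth as JSON + PNG
#'
#' Motion trace and waveform go to JSON; the true tissue ROI to PNG.
#'
#' @param truth Ground-truth list from [render_video()].
#' @param dir Output directory (created if needed).
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(motion = truth$motion, waveform = truth$waveform),
    file.path(dir, "ground_truth.json"), digits = NA, dataframe = "columns")
  write_mask_png(truth$roi, file.path(dir, "true_roi.png"))
  invisible(dir)
}
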