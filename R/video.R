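#' Fundus video sequence container
#'
#' An ordered stack of equally timed grayscale frames on a fixed pixel grid,
#' stored as a rows x cols x n numeric array in grey levels, with the frame
#' rate and per-frame quality flags (`"ok"`, `"blink"`, `"blur"`,
#' `"edge_loss"`). Registered sequences additionally carry a logical
#' validity array of the same shape marking pixels that stayed in the field
#' of view after warping.
#'
#' @param frames rows x cols x n numeric array (n >= 2) of grey levels.
#' @param fps Frames per second (> 0).
#' @param flags Optional character vector of per-frame quality flags.
#' @param valid Optional logical array, same dim as `frames`.
#' @return Object of class `video_sequence`.
#' @export
video_sequence <- function(frames, fps, flags = NULL, valid = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("video_sequence: frames must be a rows x cols x n array")
  n <- dim(frames)[3]
  if (n < 2L) stop("video_sequence: need >= 2 frames")
  if (!is.numeric(fps) || fps <= 0) stop("video_sequence: fps must be > 0")
  if (is.null(flags)) flags <- rep("ok", n)
  if (length(flags) != n) stop("video_sequence: one flag per frame required")
  bad <- setdiff(unique(flags), c("ok", "blink", "blur", "edge_loss"))
  if (length(bad)) stop("video_sequence: unknown flags: ",
                        paste(bad, collapse = ", "))
  if (!is.null(valid) && !identical(dim(valid), dim(frames)))
    stop("video_sequence: valid must match frames in shape")
  structure(list(frames = frames, fps = fps, flags = flags, valid = valid),
            class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "video_sequence: %d frames of %dx%d px at %g fps (%.1f s); flags: %s\n",
    d[3], d[1], d[2], x$fps, d[3] / x$fps,
    paste(sprintf("%s=%d", names(table(x$flags)), table(x$flags)),
          collapse = " ")))
  invisible(x)
}

n_frames <- function(video) dim(video$frames)[3]

#' Read / write a grayscale video as multi-page TIFF
#'
#' Lossless multi-page TIFF is the preferred interchange format: lossy
#' codecs corrupt the sub-percent intensity modulation the analysis
#' measures. Grey levels are stored normalized to the given bit depth.
#'
#' @param path TIFF file path.
#' @param fps Frame rate to attach on read (TIFF carries no timing).
#' @param video A [video_sequence].
#' @param max_grey Full-scale grey level used for normalization
#'   (default 255).
#' @param bits.per.sample 8 or 16.
#' @return `read_video_tiff` returns a [video_sequence]; `write_video_tiff`
#'   returns `path` invisibly.
#' @export
read_video_tiff <- function(path, fps = 25, max_grey = 255) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * max_grey
  }, matrix(0, nrow(pages[[1]]), ncol(pages[[1]])))
  video_sequence(frames, fps = fps)
}

#' @rdname read_video_tiff
#' @export
write_video_tiff <- function(video, path, max_grey = 255,
                             bits.per.sample = 16) {
  stopifnot(inherits(video, "video_sequence"))
  lst <- lapply(seq_len(n_frames(video)), function(i) {
    m <- video$frames[, , i] / max_grey
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(lst, path, bits.per.sample = bits.per.sample,
                  compression = "none")
  invisible(path)
}
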