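#' Binary region-of-interest mask
#'
#' A logical pixel mask on the frame grid, tagged with what it delineates
#' (`onh`, `vessels`, `vessels_dilated`, or the merged `onh_tissue_roi`)
#' and where it came from (`manual`, `automatic`, `merged`).
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param kind One of `"onh"`, `"vessels"`, `"vessels_dilated"`,
#'   `"onh_tissue_roi"`.
#' @param provenance One of `"manual"`, `"automatic"`, `"merged"`.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(mask, kind = c("onh", "vessels", "vessels_dilated",
                                    "onh_tissue_roi"),
                     provenance = c("manual", "automatic", "merged")) {
  kind <- match.arg(kind)
  provenance <- match.arg(provenance)
  if (!is.matrix(mask)) stop("roi_mask: mask must be a matrix")
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  structure(list(mask = m, kind = kind, provenance = provenance),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask [%s, %s]: %d / %d px\n", x$kind, x$provenance,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Read / write binary masks as PNG
#'
#' Convention: 0 = background, 255 (white) = mask.
#'
#' @param path PNG path.
#' @param kind,provenance Passed to [roi_mask()] on read.
#' @param mask A [roi_mask].
#' @export
read_mask_png <- function(path, kind = "onh", provenance = "manual") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  roi_mask(m > 0.5, kind = kind, provenance = provenance)
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}

#' Average the frames of a registered sequence
#'
#' Pixel-wise mean over artifact-free (`ok`) frames only; pixels that left
#' the field of view in a frame are excluded from that frame's
#' contribution. Averaging N frames reduces sensor noise by sqrt(N),
#' giving one representative retinal image for segmentation.
#'
#' @param video A registered [video_sequence].
#' @return Numeric matrix (grey levels); pixels valid in no frame are `NA`.
#' @export
average_frames <- function(video) {
  stopifnot(inherits(video, "video_sequence"))
  ok <- which(video$flags == "ok")
  if (!length(ok)) stop("average_frames: no artifact-free frames")
  f <- video$frames[, , ok, drop = FALSE]
  if (is.null(video$valid)) {
    return(apply(f, c(1, 2), mean))
  }
  v <- video$valid[, , ok, drop = FALSE]
  num <- apply(f * v, c(1, 2), sum)
  den <- apply(v, c(1, 2), sum)
  out <- num / den
  out[den == 0] <- NA
  out
}

# fill the convex hull of a set of (row, col) points on a pixel grid
.fill_convex_hull <- function(pts, dims) {
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]              # clockwise vertex order
  k <- nrow(poly)
  out <- matrix(TRUE, dims[1], dims[2])
  pr <- as.vector(row(out)); pc <- as.vector(col(out))
  inside <- rep(TRUE, length(pr))
  for (i in seq_len(k)) {
    a <- poly[i, ]; b <- poly[if (i == k) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (pc - a[2]) - (b[2] - a[2]) * (pr - a[1])
    inside <- inside & (cr <= 1e-9)           # clockwise: inside is right side
  }
  matrix(inside, dims[1], dims[2])
}

#' Segment the optic nerve head
#'
#' Manual-first: a supplied manual mask is validated (matching shape,
#' non-empty, a single connected component after hole filling) and passed
#' through. Without one, an automatic fallback thresholds the averaged
#' image at a brightness quantile (the ONH is the brightest large
#' structure), keeps the largest connected component and fills its convex
#' hull.
#'
#' @param avg Averaged image from [average_frames()].
#' @param manual_mask Optional [roi_mask] drawn by an expert.
#' @param quantile Brightness quantile for the automatic threshold
#'   (default 0.90).
#' @return A [roi_mask] of kind `onh` with provenance `manual` or
#'   `automatic`.
#' @export
segment_onh <- function(avg, manual_mask = NULL, quantile = 0.90) {
  if (!is.null(manual_mask)) {
    stopifnot(inherits(manual_mask, "roi_mask"))
    m <- manual_mask$mask
    if (!identical(dim(m), dim(avg)))
      stop("segment_onh: manual mask shape does not match the image")
    if (!any(m)) stop("segment_onh: manual mask is empty")
    filled <- EBImage::fillHull(m * 1) > 0
    lab <- EBImage::bwlabel(filled * 1)
    if (max(lab) != 1L)
      stop("segment_onh: manual mask must be a single connected component; ",
           "found ", max(lab))
    return(roi_mask(filled, kind = "onh", provenance = "manual"))
  }
  x <- avg
  x[is.na(x)] <- stats::median(x, na.rm = TRUE)
  hull_at <- function(thr) {
    bw <- (x >= thr) * 1
    # vessels slice the bright disc into sectors; close across them before
    # picking the largest component
    bw <- EBImage::closing(bw, .disc_kernel(4))
    lab <- EBImage::bwlabel(bw)
    if (max(lab) == 0) stop("segment_onh: threshold produced an empty mask")
    sizes <- tabulate(lab[lab > 0])
    pts <- which(lab == which.max(sizes), arr.ind = TRUE)
    .fill_convex_hull(pts, dim(avg))
  }
  # seed at the brightness quantile, then re-threshold midway between the
  # inside and outside means so the full disc is recovered even when the
  # quantile seed caught only its brightest patch
  hull <- hull_at(stats::quantile(x, quantile))
  hull <- hull_at((mean(x[hull]) + mean(x[!hull])) / 2)
  roi_mask(hull, kind = "onh", provenance = "automatic")
}

# multiscale Hessian ridge response to bright curvilinear structures
.vesselness <- function(img, scales) {
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    sm <- as.matrix(EBImage::gblur(img, s))
    nr <- nrow(sm); nc <- ncol(sm)
    pad_r <- sm[c(1, 1:nr, nr), ]
    pad_c <- sm[, c(1, 1:nc, nc)]
    Ixx <- pad_r[1:nr, ] - 2 * sm + pad_r[3:(nr + 2), ]
    Iyy <- pad_c[, 1:nc] - 2 * sm + pad_c[, 3:(nc + 2)]
    padb <- sm[c(1, 1:nr, nr), c(1, 1:nc, nc)]
    Ixy <- (padb[3:(nr + 2), 3:(nc + 2)] + padb[1:nr, 1:nc] -
            padb[1:nr, 3:(nc + 2)] - padb[3:(nr + 2), 1:nc]) / 4
    disc <- sqrt(pmax((Ixx - Iyy)^2 + 4 * Ixy^2, 0))
    lam_min <- ((Ixx + Iyy) - disc) / 2
    best <- pmax(best, s^2 * pmax(-lam_min, 0))
  }
  best
}

#' Segment the retinal vessel tree
#'
#' Vessels are dark curvilinear structures on the fundus; the inverted
#' image is filtered with a multiscale Hessian ridge (vesselness) measure
#' and binarized by hysteresis: connected components of the low-threshold
#' map are kept only when they contain high-threshold seed pixels and
#' exceed a minimum size (vessels are long; noise speckle is not).
#' Thresholds are expressed as fractions of the median grey level, i.e. as
#' absorption contrast: a large vessel dims the image locally by tens of
#' percent, while background texture and noise stay in the low single
#' digits, so a constant or vessel-free image yields an (almost) empty
#' mask.
#'
#' @param avg Averaged image.
#' @param scales Gaussian scales in px for the ridge filter.
#' @param high_frac,low_frac Seed and growth thresholds on the ridge
#'   response, as fractions of the median grey level (defaults 0.08 and
#'   0.02).
#' @param min_size Minimum component size in px.
#' @return A [roi_mask] of kind `vessels` (possibly empty).
#' @export
segment_vessels <- function(avg, scales = c(1, 2, 3), high_frac = 0.08,
                            low_frac = 0.02, min_size = 30) {
  x <- avg
  x[is.na(x)] <- stats::median(x, na.rm = TRUE)
  v <- .vesselness(max(x) - x, scales)
  # vessels are darker than their local surround; this gate removes the
  # ridge-like shoulder responses that flank bright/dark boundaries such
  # as the disc rim
  rng <- diff(range(x))
  if (rng == 0)
    return(roi_mask(matrix(FALSE, nrow(avg), ncol(avg)), kind = "vessels",
                    provenance = "automatic"))
  med_grey <- stats::median(x)
  xs <- (x - min(x)) / rng
  locmed <- as.matrix(EBImage::medianFilter(xs, max(scales) * 3)) * rng + min(x)
  # margin: a vessel centreline must undercut its local median by a real
  # absorption contrast, which edge shoulders and texture do not
  v[x >= locmed - low_frac * med_grey] <- 0
  hi <- v >= high_frac * med_grey
  lo <- v >= low_frac * med_grey
  lab <- EBImage::bwlabel(lo * 1)
  keep <- setdiff(unique(lab[hi]), 0)
  if (length(keep)) {
    sizes <- tabulate(lab[lab > 0])
    keep <- keep[sizes[keep] >= min_size]
  }
  roi_mask(matrix(lab %in% keep, nrow(avg), ncol(avg)),
           kind = "vessels", provenance = "automatic")
}

# Euclidean disc structuring element as a 0/1 kernel matrix
.disc_kernel <- function(radius) {
  r <- ceiling(radius)
  d <- 2 * r + 1
  off <- seq(-r, r)
  k <- outer(off^2, off^2, "+") <= radius^2 + 1e-9
  matrix(as.numeric(k), d, d)
}

#' Dilate the vessel mask
#'
#' Morphological dilation with a circular (Euclidean disc) structuring
#' element, enlarging the vessel tree so that the pulsating, moving
#' immediate surroundings of large vessels are excluded from the tissue
#' ROI. The default element is 5 px in size read as the diameter
#' (radius 2, 13 px); set `interpret = "radius"` for the wider reading.
#'
#' @param vessels A [roi_mask] of kind `vessels`.
#' @param size_px Structuring-element size in px (default 5).
#' @param interpret `"diameter"` (default) or `"radius"`.
#' @return A [roi_mask] of kind `vessels_dilated` (superset of the input).
#' @export
dilate_vessels <- function(vessels, size_px = 5,
                           interpret = c("diameter", "radius")) {
  stopifnot(inherits(vessels, "roi_mask"))
  interpret <- match.arg(interpret)
  radius <- if (interpret == "diameter") (size_px - 1) / 2 else size_px
  if (!any(vessels$mask))
    return(roi_mask(vessels$mask, kind = "vessels_dilated",
                    provenance = vessels$provenance))
  kern <- .disc_kernel(radius)
  out <- EBImage::dilate(vessels$mask * 1, kern) > 0
  roi_mask(out, kind = "vessels_dilated", provenance = vessels$provenance)
}

#' Merge ONH and dilated-vessel masks into the tissue ROI
#'
#' The analysis region is the ONH microvascular tissue: ONH pixels that do
#' not belong to the dilated vessel tree. A ROI smaller than `min_px`
#' aborts, because the aggregated signal of a tiny region is
#' noise-dominated.
#'
#' @param onh A [roi_mask] of kind `onh`.
#' @param vessels_dilated A [roi_mask] of kind `vessels_dilated` (or
#'   `vessels`).
#' @param min_px Minimum ROI pixel count (default 500).
#' @return A [roi_mask] of kind `onh_tissue_roi`, provenance `merged`.
#' @export
make_onh_roi <- function(onh, vessels_dilated, min_px = 500) {
  stopifnot(inherits(onh, "roi_mask"), inherits(vessels_dilated, "roi_mask"))
  if (!identical(dim(onh$mask), dim(vessels_dilated$mask)))
    stop("make_onh_roi: mask shapes differ")
  m <- onh$mask & !vessels_dilated$mask
  if (sum(m) < min_px)
    stop("make_onh_roi: tissue ROI has ", sum(m), " px (< ", min_px,
         "); signal would be noise-dominated")
  roi_mask(m, kind = "onh_tissue_roi", provenance = "merged")
}
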