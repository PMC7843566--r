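#' Rigid (shift + rotation) frame registration
#'
#' Eye movements during acquisition shift and rotate the retinal image from
#' frame to frame; they must be suppressed before any per-pixel intensity
#' trace is meaningful. The estimator here is phase correlation (Hann
#' windowed, with local upsampled-DFT refinement for subpixel translation)
#' combined with a coarse-to-fine search over rotation angles that
#' maximizes the phase-correlation peak height, refined by a parabola fit.
#'
#' Conventions: `dx` is the column (horizontal) shift, `dy` the row
#' (vertical) shift in pixels; `theta` is the rotation in degrees about the
#' frame centre. [estimate_rigid()] returns the motion of the moving frame
#' relative to the reference (i.e. `moving ~ apply_rigid(reference, dx, dy,
#' theta)`); [register_sequence()] applies the inverse transform to bring
#' every frame into the reference frame's coordinates.
#'
#' @name registration
NULL

# forward rigid warp: rotate by theta (deg) about the frame centre, then
# translate by (dy rows, dx cols); bilinear interpolation, background 0
rigid_affine_matrix <- function(dx, dy, theta_deg, dims) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  A <- t(R)
  ctr <- matrix((dims + 1) / 2, 1, 2)     # (row, col) centre
  b <- ctr - ctr %*% A + c(dy, dx)
  rbind(A, b)
}

#' Apply a rigid transform to a frame
#'
#' @param img Numeric matrix (grey levels).
#' @param dx,dy Translation in pixels (columns, rows).
#' @param theta Rotation in degrees about the frame centre.
#' @return Warped matrix, same shape; out-of-field pixels are 0. Attribute
#'   `"valid"` is a logical matrix of in-field pixels.
#' @export
apply_rigid <- function(img, dx, dy, theta) {
  m <- rigid_affine_matrix(dx, dy, theta, dim(img))
  out <- EBImage::affine(img, m, filter = "bilinear", output.dim = dim(img))
  ones <- EBImage::affine(matrix(1, nrow(img), ncol(img)), m,
                          filter = "bilinear", output.dim = dim(img))
  out <- as.matrix(out)
  attr(out, "valid") <- as.matrix(ones) > 0.999
  out
}

# inverse of a rigid transform in the same parameterization
invert_rigid <- function(dx, dy, theta) {
  th <- -theta * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  t2 <- -R %*% c(dy, dx)
  list(dx = t2[2], dy = t2[1], theta = -theta)
}

.hann2 <- function(nr, nc) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  outer(wr, wc)
}

.fftfreq_idx <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n)
}

# normalized cross-power spectrum of reference vs moving (windowed)
.cross_power <- function(ref, mov, window) {
  F1 <- stats::fft((ref - mean(ref)) * window)
  F2 <- stats::fft((mov - mean(mov)) * window)
  X <- F1 * Conj(F2)
  X / (Mod(X) + 1e-12)
}

# integer-pixel phase-correlation peak: list(shift = c(dy, dx), peak)
.pc_peak <- function(Xn) {
  r <- Re(stats::fft(Xn, inverse = TRUE)) / length(Xn)
  k <- arrayInd(which.max(r), dim(r)) - 1L
  d <- dim(r)
  wrap <- ifelse(k > d / 2, k - d, k)
  list(shift = -as.numeric(wrap), peak = max(r))
}

# upsampled local DFT refinement of the correlation surface around the
# integer peak position p0 (Guizar-Sicairos style); returns the refined
# peak POSITION (the shift estimate is its negation)
.pc_refine <- function(Xn, p0, usfac = 50, halfwidth = 1.5) {
  d <- dim(Xn)
  fr <- .fftfreq_idx(d[1]) / d[1]
  fc <- .fftfreq_idx(d[2]) / d[2]
  du <- seq(-halfwidth, halfwidth, by = 1 / usfac)
  # CC(p) = (1/N) sum Xn[k, l] exp(2i pi (fr[k] p_r + fc[l] p_c))
  Er <- exp(2i * pi * outer(du + p0[1], fr))         # |du| x nr
  Ec <- exp(2i * pi * outer(fc, du + p0[2]))         # nc x |dv|
  CC <- Re(Er %*% Xn %*% Ec) / length(Xn)
  k <- arrayInd(which.max(CC), dim(CC))
  list(pos = c(p0[1] + du[k[1]], p0[2] + du[k[2]]), peak = max(CC))
}

# parabola vertex through three points (x equally spaced)
.parabola_vertex <- function(x, y) {
  denom <- (y[1] - 2 * y[2] + y[3])
  if (abs(denom) < 1e-15) return(x[2])
  x[2] + 0.5 * (y[1] - y[3]) / denom * (x[3] - x[1]) / 2
}

# bilinear sampling grid over the upper half-plane of the (unshifted)
# frequency domain: n_angles x n_radii sample points with wrap-around
.make_polar_grid <- function(dims, n_angles = 720,
                             rfrac = c(0.08, 0.30)) {
  ang <- pi * (seq_len(n_angles) - 1) / n_angles      # [0, pi)
  rad <- seq(rfrac[1], rfrac[2], by = 1 / min(dims)) * min(dims)
  fr <- outer(cos(ang), rad)                           # rows of freq plane
  fc <- outer(sin(ang), rad)
  r0 <- floor(fr); c0 <- floor(fc)
  wr <- fr - r0; wc <- fc - c0
  idx <- function(r, c2) {
    cbind(as.vector(r %% dims[1]) + 1L, as.vector(c2 %% dims[2]) + 1L)
  }
  list(n_angles = n_angles, shape = dim(fr),
       i00 = idx(r0, c0), i10 = idx(r0 + 1, c0),
       i01 = idx(r0, c0 + 1), i11 = idx(r0 + 1, c0 + 1),
       w00 = as.vector((1 - wr) * (1 - wc)), w10 = as.vector(wr * (1 - wc)),
       w01 = as.vector((1 - wr) * wc), w11 = as.vector(wr * wc))
}

# angular energy profile of the log magnitude spectrum
.angular_profile <- function(M, g) {
  L <- log1p(M)
  s <- L[g$i00] * g$w00 + L[g$i10] * g$w10 +
       L[g$i01] * g$w01 + L[g$i11] * g$w11
  rowMeans(matrix(s, nrow = g$shape[1]))
}

# rotation between two frames from the angular correlation of their
# magnitude spectra (Fourier-Mellin without the scale axis); degrees
.estimate_rotation <- function(ref, mov, window, grid, theta_range) {
  p1 <- .angular_profile(Mod(stats::fft((ref - mean(ref)) * window)), grid)
  p2 <- .angular_profile(Mod(stats::fft((mov - mean(mov)) * window)), grid)
  p1 <- p1 - mean(p1); p2 <- p2 - mean(p2)
  na <- grid$n_angles
  step <- 180 / na
  max_lag <- min(na %/% 2 - 1L, ceiling(theta_range / step))
  lags <- -max_lag:max_lag
  sc <- vapply(lags, function(l) {
    sum(p2 * p1[((seq_len(na) - 1 - l) %% na) + 1])
  }, numeric(1))
  b <- which.max(sc)
  th <- if (b > 1 && b < length(sc)) {
    .parabola_vertex(lags[(b - 1):(b + 1)], sc[(b - 1):(b + 1)])
  } else lags[b]
  th * step
}

# translation between reference and (rotation-corrected) moving frame.
# The whitened cross-power is tapered by a radial Gaussian low-pass: the
# nonlinear phase that bilinear resampling imprints on high frequencies
# would otherwise bias subpixel estimates toward integer shifts. A second
# pass on the integer-shift-corrected frame confines residual window bias
# to a near-zero shift. Confidence is the peak height renormalized by the
# taper mass, so a perfect alignment scores 1.
.estimate_translation <- function(reference, m, w, f0 = 0.15) {
  d <- dim(reference)
  fr <- .fftfreq_idx(d[1]) / d[1]
  fc <- .fftfreq_idx(d[2]) / d[2]
  lp <- exp(-outer(fr^2, fc^2, "+") / (2 * f0^2))
  Xl <- .cross_power(reference, m, w) * lp
  p0 <- .pc_peak(Xl)
  s_int <- round(p0$shift)                 # (dy, dx) integer part
  if (any(s_int != 0)) {
    m <- apply_rigid(m, -s_int[2], -s_int[1], 0)
    Xl <- .cross_power(reference, m, w) * lp
    p0 <- .pc_peak(Xl)
  }
  ref1 <- .pc_refine(Xl, -p0$shift)
  list(dy = s_int[1] - ref1$pos[1], dx = s_int[2] - ref1$pos[2],
       confidence = min(1, ref1$peak * length(lp) / sum(lp)))
}

#' Estimate the rigid motion between two frames
#'
#' Rotation first, from the angular correlation of the frames' magnitude
#' spectra (which translation cannot affect), then subpixel translation by
#' phase correlation of the rotation-corrected frame.
#'
#' @param moving,reference Numeric matrices of identical shape.
#' @param rotation Search for rotation as well as translation?
#' @param theta_range Half-width of the rotation search in degrees
#'   (candidates span `(-theta_range, theta_range]`).
#' @param polar_grid Precomputed grid from the internal polar resampler;
#'   supplied by [register_sequence()] to avoid rebuilding it per frame.
#' @return List with `dx`, `dy` (px, subpixel), `theta` (degrees) and
#'   `confidence` (normalized phase-correlation peak height; 0 for a
#'   constant frame, for which the identity transform is returned).
#' @export
estimate_rigid <- function(moving, reference, rotation = TRUE,
                           theta_range = 10, polar_grid = NULL) {
  if (!identical(dim(moving), dim(reference)))
    stop("estimate_rigid: frames must have the same shape")
  if (stats::sd(moving) == 0 || stats::sd(reference) == 0) {
    return(list(dx = 0, dy = 0, theta = 0, confidence = 0))
  }
  w <- .hann2(nrow(reference), ncol(reference))
  theta <- 0
  if (rotation) {
    if (is.null(polar_grid)) polar_grid <- .make_polar_grid(dim(reference))
    # iterate on the residual: the angular-correlation bias shrinks as the
    # remaining rotation approaches zero
    for (it in 1:3) {
      m <- if (theta == 0) moving else apply_rigid(moving, 0, 0, -theta)
      dth <- .estimate_rotation(reference, m, w, polar_grid, theta_range)
      theta <- theta + dth
      if (abs(dth) < 0.02) break
    }
  }
  m <- if (theta == 0) moving else apply_rigid(moving, 0, 0, -theta)
  tr <- .estimate_translation(reference, m, w)
  list(dx = tr$dx, dy = tr$dy, theta = theta, confidence = tr$confidence)
}

#' Flag distorted frames (blink / motion or focus blur)
#'
#' Eye blinks produce near-saturated frames (strong eyelid reflection);
#' fast eye movement or defocus wipes out image gradients. A frame is
#' flagged `blink` when its mean grey level exceeds `blink_ratio` times the
#' median frame mean, and `blur` when its gradient energy falls below
#' `blur_frac` times the median gradient energy of non-blink frames.
#'
#' @param video A [video_sequence].
#' @param blink_ratio Relative brightness threshold (default 1.15).
#' @param blur_frac Gradient-energy fraction threshold (default 0.5).
#' @return Character vector of per-frame flags.
#' @export
flag_artifacts <- function(video, blink_ratio = 1.15, blur_frac = 0.5) {
  stopifnot(inherits(video, "video_sequence"))
  n <- n_frames(video)
  means <- apply(video$frames, 3, mean)
  grad <- apply(video$frames, 3, function(f) {
    mean(diff(f)^2) + mean(t(diff(t(f)))^2)
  })
  flags <- rep("ok", n)
  flags[means > blink_ratio * stats::median(means)] <- "blink"
  gmed <- stats::median(grad[flags == "ok"])
  flags[flags == "ok" & grad < blur_frac * gmed] <- "blur"
  flags
}

#' Register a video sequence to a common reference frame
#'
#' The reference is the temporally middle artifact-free frame. Every frame
#' is aligned to it by the inverse of its estimated rigid motion (bilinear
#' resampling); out-of-field pixels are marked invalid and excluded from
#' all downstream ROI statistics. Frames with low registration confidence
#' or large out-of-field loss are flagged `edge_loss`, never dropped, so
#' the frame clock stays intact for pulse timing.
#'
#' @param video A [video_sequence].
#' @param rotation Include rotation in the motion model (default TRUE).
#' @param theta_range Rotation search half-width, degrees.
#' @param conf_threshold Confidence below which a frame is flagged
#'   (default 0.3).
#' @param refresh_flags Re-run [flag_artifacts()] and merge with existing
#'   flags (default TRUE).
#' @return List with `video` (registered [video_sequence] with validity
#'   array and updated flags) and `trace` (data frame `frame, dx_px, dy_px,
#'   theta_deg, confidence, flag`).
#' @export
register_sequence <- function(video, rotation = TRUE, theta_range = 10,
                              conf_threshold = 0.3,
                              refresh_flags = TRUE) {
  stopifnot(inherits(video, "video_sequence"))
  n <- n_frames(video)
  flags <- video$flags
  if (refresh_flags) {
    auto <- flag_artifacts(video)
    flags <- ifelse(flags == "ok", auto, flags)
  }
  ok <- which(flags == "ok")
  if (!length(ok))
    stop("register_sequence: no artifact-free frames; cannot pick a reference")
  ref_idx <- ok[ceiling(length(ok) / 2)]
  ref <- video$frames[, , ref_idx]

  out <- array(0, dim(video$frames))
  valid <- array(TRUE, dim(video$frames))
  trace <- data.frame(frame = seq_len(n), dx_px = 0, dy_px = 0,
                      theta_deg = 0, confidence = 1, flag = flags,
                      stringsAsFactors = FALSE)
  pg <- if (rotation) .make_polar_grid(dim(ref))
  for (i in seq_len(n)) {
    if (i == ref_idx) {
      out[, , i] <- ref
      next
    }
    est <- estimate_rigid(video$frames[, , i], ref, rotation = rotation,
                          theta_range = theta_range, polar_grid = pg)
    inv <- invert_rigid(est$dx, est$dy, est$theta)
    warped <- apply_rigid(video$frames[, , i], inv$dx, inv$dy, inv$theta)
    out[, , i] <- warped
    valid[, , i] <- attr(warped, "valid")
    trace$dx_px[i] <- est$dx
    trace$dy_px[i] <- est$dy
    trace$theta_deg[i] <- est$theta
    trace$confidence[i] <- est$confidence
    if (flags[i] == "ok" &&
        (est$confidence < conf_threshold ||
         mean(valid[, , i]) < 0.75)) {
      flags[i] <- "edge_loss"
    }
  }
  trace$flag <- flags
  list(video = video_sequence(out, fps = video$fps, flags = flags,
                              valid = valid),
       trace = trace)
}

#' Write a motion trace as CSV
#'
#' Columns: `frame,dx_px,dy_px,theta_deg,confidence,flag`.
#'
#' @param trace Motion-trace data frame from [register_sequence()].
#' @param path Output CSV path.
#' @export
write_motion_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
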