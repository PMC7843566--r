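# Shared fixtures and independent oracles for the test suite.

# structured fundus-like test frame: bright disc, two dark vessels
make_test_frame <- function(nr = 100, nc = 100, blur = 1) {
  rr <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))
  img <- matrix(120, nr, nc)
  d <- sqrt((rr - nr / 2)^2 + (cc - nc / 2)^2)
  img[d < 0.3 * nr] <- 190
  img[abs(rr - cc) < 2 & d < 0.45 * nr] <- 80
  img[abs(rr + cc - nr) < 2 & d < 0.45 * nr] <- 80
  img[abs(cc - 0.6 * nc) < 1.5 & d < 0.45 * nr] <- 85
  as.matrix(EBImage::gblur(img, blur))
}

# standard clean phantom video: triangle beat with on-grid peak so the
# sampled trace attains the full amplitude
make_phantom_video <- function(n_frames = 250, amplitude = 5,
                               time_to_peak = 0.32, fwhm = 0.5,
                               duration = 1.0, fps = 25, noise_sd = 0,
                               dx = 0, dy = 0, theta = 0,
                               blink_frames = integer(0),
                               blur_frames = integer(0), seed = 11,
                               frame_shape = c(100L, 100L),
                               texture_amp = 0.03, shape = "triangle") {
  spec <- waveform_spec(amplitude, time_to_peak, duration, fwhm = fwhm,
                        shape = shape)
  wave <- tile_waveform(generate_pulse_waveform(spec, fps), n_frames)
  art <- motion_artifact_spec(dx = dx, dy = dy, theta = theta, n = n_frames,
                              blink_frames = blink_frames,
                              blur_frames = blur_frames,
                              noise_sd = noise_sd, seed = seed)
  ph <- scene_phantom(frame_shape = frame_shape,
                      onh_radius = round(0.3 * frame_shape[1]),
                      texture_amp = texture_amp)
  c(render_video(ph, wave, art), list(spec = spec, wave = wave))
}

# dense-grid crossing-search oracle for pulse parameters: no interpolation,
# nearest-sample crossings only (independent of the package's extractors)
oracle_pulse_parameters <- function(values, dt) {
  k_peak <- which.max(values)
  amp <- values[k_peak]
  half <- amp / 2
  up <- which(values[1:k_peak] >= half)[1]
  dn_rel <- which(values[k_peak:length(values)] <= half)[1]
  dn <- k_peak + dn_rel - 1L
  list(amplitude = amp,
       ttp = (k_peak - 1) * dt,
       fwhm = (dn - up) * dt,
       duration = (length(values) - 1) * dt)
}

# exact two-sample Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Kruskal-Wallis H by direct rank arithmetic (no tie correction needed for
# distinct values)
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  s <- tapply(r, groups, sum)
  ni <- tapply(r, groups, length)
  12 / (n * (n + 1)) * sum(s^2 / ni) - 3 * (n + 1)
}

# brute-force binary dilation: OR of the mask shifted by every offset of a
# Euclidean disc of the given radius
oracle_dilate <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  r <- ceiling(radius)
  for (di in -r:r) for (dj in -r:r) {
    if (di^2 + dj^2 > radius^2 + 1e-9) next
    src_r <- seq_len(nr) - di
    src_c <- seq_len(nc) - dj
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    out[ok_r, ok_c] <- out[ok_r, ok_c] | mask[src_r[ok_r], src_c[ok_c]]
  }
  out
}

# a minimal pleth_signal from a bare %A trace
make_sig <- function(a, fps = 25, flags = rep("ok", length(a))) {
  pleth_signal(i_raw = 100 - a, i_trend = rep(100, length(a)),
               a_pct = a, display_100 = 100 + a, fps = fps,
               frame_flags = flags)
}
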