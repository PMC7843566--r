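#' Pipeline run configuration
#'
#' One object carries every stage default; all randomness funnels through
#' `seed`. Defaults follow the acquisition and processing conventions the
#' analysis was designed around: 25 frames/s, a 1.5 s trend window, the
#' 30-70% rise steepness estimator, a 5 px (diameter) vessel dilation, and
#' 2-7 accepted pulses.
#'
#' @param fps Frames per second of the input video.
#' @param trend_window_s Trend moving-average window, seconds.
#' @param steepness_variant Steepness estimator (see [pulse_steepness()]).
#' @param dilation_px Vessel dilation structuring-element size, px.
#' @param dilation_interpret `"diameter"` or `"radius"`.
#' @param min_roi_px Minimum tissue-ROI size.
#' @param selection `"auto"` or `"manual"` pulse selection.
#' @param min_pulses,max_pulses Accepted pulse-count range.
#' @param rotation Estimate rotation during registration.
#' @param auto_onh Allow automatic ONH segmentation when no manual mask is
#'   given.
#' @param bonferroni_family `"per_parameter"` or `"global"`.
#' @param seed Integer seed.
#' @param out_dir Output directory for file-based runs.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(fps = 25, trend_window_s = 1.5,
                       steepness_variant = "rise_30_70",
                       dilation_px = 5, dilation_interpret = "diameter",
                       min_roi_px = 500, selection = c("auto", "manual"),
                       min_pulses = 2L, max_pulses = 7L, rotation = TRUE,
                       auto_onh = TRUE,
                       bonferroni_family = c("per_parameter", "global"),
                       seed = 1L, out_dir = NULL) {
  structure(list(fps = fps, trend_window_s = trend_window_s,
                 steepness_variant = steepness_variant,
                 dilation_px = dilation_px,
                 dilation_interpret = dilation_interpret,
                 min_roi_px = min_roi_px, selection = match.arg(selection),
                 min_pulses = as.integer(min_pulses),
                 max_pulses = as.integer(max_pulses), rotation = rotation,
                 auto_onh = auto_onh,
                 bonferroni_family = match.arg(bonferroni_family),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Fields present in the file override [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("read_run_config: unknown fields: ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full per-sequence analysis
#'
#' Executes the pipeline stages in order on an in-memory video: artifact
#' flagging and rigid registration, frame averaging, ONH / vessel
#' segmentation and ROI merge, trend-corrected signal extraction, pulse
#' detection/selection/averaging, and parameter extraction.
#'
#' @param video A [video_sequence].
#' @param onh_mask Optional manual ONH [roi_mask]; required when
#'   `config$auto_onh` is `FALSE`.
#' @param vessel_mask Optional manual vessel [roi_mask]; segmented
#'   automatically when absent.
#' @param labels Optional manual [pulse_labels].
#' @param config A [run_config()].
#' @return List of class `onh_analysis` with elements `registered`,
#'   `trace`, `avg_image`, `masks` (onh, vessels, vessels_dilated, roi),
#'   `signal`, `labels`, `pulse`, `parameters` (one-row data frame
#'   including `pulse_rate_bpm`), and `provenance`.
#' @export
analyze_video <- function(video, onh_mask = NULL, vessel_mask = NULL,
                          labels = NULL, config = run_config()) {
  stopifnot(inherits(video, "video_sequence"), inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("analyze_video [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(onh_mask) && !config$auto_onh)
    stop("analyze_video [segment_onh]: no manual ONH mask supplied and ",
         "automatic segmentation is disabled")
  reg <- stage("register", register_sequence(video, rotation = config$rotation))
  avg <- stage("average", average_frames(reg$video))
  onh <- stage("segment_onh", segment_onh(avg, manual_mask = onh_mask))
  vess <- if (is.null(vessel_mask)) {
    stage("segment_vessels", segment_vessels(avg))
  } else vessel_mask
  vdil <- stage("dilate", dilate_vessels(vess, size_px = config$dilation_px,
                                         interpret = config$dilation_interpret))
  roi <- stage("merge_roi", make_onh_roi(onh, vdil, min_px = config$min_roi_px))
  stopifnot(!any(roi$mask & vdil$mask), all(onh$mask[roi$mask]))
  i_raw <- stage("intensity", extract_intensity_signal(reg$video, roi))
  i_trend <- stage("trend",
                   estimate_trend(i_raw, fps = video$fps,
                                  window_s = config$trend_window_s))
  sig <- stage("pleth", compute_pleth_signal(i_raw, i_trend, fps = video$fps))
  pick <- function(s) {
    if (!is.null(labels) || config$selection == "manual") {
      if (is.null(labels))
        stop("analyze_video [select_pulses]: manual selection requested ",
             "but no labels supplied")
      stage("select_pulses", select_pulses(NULL, s, labels = labels))
    } else {
      minima <- stage("detect_minima", detect_minima(s))
      stage("select_pulses",
            select_pulses(minima, s, min_pulses = config$min_pulses,
                          max_pulses = config$max_pulses))
    }
  }
  lab <- pick(sig)
  # period-locked second pass: a boxcar spanning an integer number of beat
  # periods has a spectral null at the pulse rate, so the trend no longer
  # leaks (and thereby distorts) the cardiac fundamental. Among the first
  # few multiples of the period, pick the one whose odd-forced frame count
  # stays closest to an exact multiple.
  period_s <- 60 / pulse_rate(lab)
  pf <- period_s * video$fps
  k0 <- max(1, ceiling(config$trend_window_s / period_s))
  cand_k <- k0:(k0 + 3)
  cand_k <- cand_k[round(cand_k * pf) + 1 <= length(i_raw)]
  if (!length(cand_k)) cand_k <- k0
  leak <- vapply(cand_k, function(k) {
    w <- round(k * pf)
    if (w %% 2 == 0) w <- w + 1
    abs(sin(pi * w / pf) / (pi * w / pf))
  }, numeric(1))
  k <- cand_k[which.min(leak)]
  i_trend <- stage("trend",
                   estimate_trend(i_raw, fps = video$fps,
                                  window_s = k * period_s))
  sig <- stage("pleth", compute_pleth_signal(i_raw, i_trend, fps = video$fps))
  lab <- pick(sig)
  pulse <- stage("average_pulses",
                 average_pulses(sig, lab, min_pulses = config$min_pulses))
  pars <- stage("parameters",
                extract_pulse_parameters(pulse, variant = config$steepness_variant))
  pars$pulse_rate_bpm <- pulse_rate(lab)
  structure(list(registered = reg$video, trace = reg$trace, avg_image = avg,
                 masks = list(onh = onh, vessels = vess,
                              vessels_dilated = vdil, roi = roi),
                 signal = sig, labels = lab, pulse = pulse, parameters = pars,
                 provenance = list(config = unclass(config),
                                   n_frames = n_frames(video),
                                   label_source = lab$source,
                                   package_version =
                                     as.character(utils::packageVersion("onhpleth")))),
            class = "onh_analysis")
}

#' @export
print.onh_analysis <- function(x, ...) {
  cat("ONH plethysmography analysis\n")
  print(x$pulse)
  p <- x$parameters
  cat(sprintf(
    "  amplitude %.2f %%A | steepness %.1f %%A/s (%s) | TTP %.2f s (%.0f%%) | FWHM %.2f s (%.0f%%) | duration %.2f s | %.0f bpm\n",
    p$peak_amplitude, p$steepness, p$steepness_variant, p$ttp_s, p$ttp_pct,
    p$fwhm_s, p$fwhm_pct, p$duration_s, p$pulse_rate_bpm))
  invisible(x)
}

#' File-based analysis run
#'
#' Reads a multi-page TIFF video and optional PNG masks / JSON labels,
#' runs [analyze_video()], and writes every intermediate product plus a
#' JSON provenance record into `config$out_dir`.
#'
#' @param video_path Multi-page TIFF path.
#' @param onh_mask_path,vessel_mask_path Optional PNG mask paths.
#' @param labels_path Optional pulse-label JSON path.
#' @param config A [run_config()]; `out_dir` must be set.
#' @return The `onh_analysis` object, invisibly.
#' @export
analyze_video_file <- function(video_path, onh_mask_path = NULL,
                               vessel_mask_path = NULL, labels_path = NULL,
                               config = run_config()) {
  if (is.null(config$out_dir))
    stop("analyze_video_file: config$out_dir must be set")
  video <- read_video_tiff(video_path, fps = config$fps)
  onh <- if (!is.null(onh_mask_path))
    read_mask_png(onh_mask_path, kind = "onh", provenance = "manual")
  vess <- if (!is.null(vessel_mask_path))
    read_mask_png(vessel_mask_path, kind = "vessels", provenance = "manual")
  labels <- if (!is.null(labels_path)) read_pulse_labels(labels_path)
  res <- analyze_video(video, onh_mask = onh, vessel_mask = vess,
                       labels = labels, config = config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_video_tiff(res$registered, file.path(out, "registered.tiff"))
  write_motion_trace(res$trace, file.path(out, "motion_trace.csv"))
  for (nm in names(res$masks))
    write_mask_png(res$masks[[nm]], file.path(out, paste0(nm, ".png")))
  write_signal_csv(res$signal, file.path(out, "signal.csv"))
  ap <- res$pulse
  utils::write.csv(
    data.frame(sample = seq_along(ap$values),
               time_s = (seq_along(ap$values) - 1) * ap$dt,
               value_pctA = ap$values, sd_pctA = ap$sd),
    file.path(out, "averaged_pulse.csv"), row.names = FALSE)
  utils::write.csv(res$parameters, file.path(out, "parameters.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(res$provenance,
                         list(inputs = list(video = video_path,
                                            onh_mask = onh_mask_path,
                                            vessel_mask = vessel_mask_path,
                                            labels = labels_path))),
                       file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

#' Batch analysis over a manifest of sequences
#'
#' The manifest CSV needs columns `subject_id, sequence_id, video` and
#' optionally `onh_mask, vessel_mask, labels`. Each sequence is analyzed
#' independently; failures are logged and the run continues. When a
#' subject has several sequences, the one with the most accepted pulses
#' is kept (the sequence-choice policy).
#'
#' @param manifest Data frame or CSV path.
#' @param config A [run_config()].
#' @return Data frame with one row per subject (cohort-table layout) and
#'   attributes `"failures"` (data frame) and `"policy"`.
#' @export
batch_analyze <- function(manifest, config = run_config()) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  if (!nrow(manifest)) stop("batch_analyze: empty manifest")
  opt <- function(row, col) {
    if (col %in% names(manifest) && nzchar(row[[col]]) && !is.na(row[[col]]))
      row[[col]] else NULL
  }
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      video <- read_video_tiff(row$video, fps = config$fps)
      onh <- if (!is.null(p <- opt(row, "onh_mask")))
        read_mask_png(p, "onh", "manual")
      vess <- if (!is.null(p <- opt(row, "vessel_mask")))
        read_mask_png(p, "vessels", "manual")
      lab <- if (!is.null(p <- opt(row, "labels"))) read_pulse_labels(p)
      analyze_video(video, onh, vess, lab, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(subject_id = row$subject_id, sequence_id = row$sequence_id,
                   error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(subject_id = row$subject_id,
                         sequence_id = row$sequence_id,
                         stringsAsFactors = FALSE),
              res$parameters)
    }
  }
  if (!length(rows)) stop("batch_analyze: every sequence failed")
  tab <- do.call(rbind, rows)
  # sequence-choice policy: most accepted pulses per subject
  keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$subject_id),
                        function(ix) ix[which.max(tab$n_pulses[ix])]))
  out <- tab[sort(keep), ]
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(subject_id = character(0), sequence_id = character(0),
               error = character(0))
  attr(out, "policy") <- "most_accepted_pulses"
  out
}

#' Group-statistics report for a cohort table
#'
#' Runs the full statistical layer on a cohort table: per-group summary
#' with omnibus Kruskal-Wallis, pairwise Mann-Whitney against the normal
#' group (Bonferroni-corrected), and Spearman correlation plus regression
#' slope of each parameter against RNFL thickness.
#'
#' @param table Cohort data frame or CSV path.
#' @param parameters Parameter columns to analyze.
#' @param reference Reference group name (default `"norm"`).
#' @param config A [run_config()] (controls the Bonferroni family).
#' @return List with `summary`, `kruskal`, `pairwise`, `correlation`.
#' @export
cohort_stats <- function(table,
                         parameters = c("peak_amplitude", "steepness",
                                        "ttp_s", "ttp_pct", "fwhm_s",
                                        "fwhm_pct", "duration_s"),
                         reference = "norm", config = run_config()) {
  if (is.character(table)) table <- utils::read.csv(table)
  parameters <- intersect(parameters, names(table))
  fam_mult <- if (config$bonferroni_family == "global") length(parameters) else 1
  cs <- cohort_summary(table, parameters)
  pw <- do.call(rbind, lapply(parameters, function(p) {
    d <- pairwise_vs_normal(table, p, reference = reference,
                            family = fam_mult *
                              (length(unique(table$group)) - 1))
    cbind(parameter = p, d, stringsAsFactors = FALSE)
  }))
  corr <- if ("rnfl_um" %in% names(table)) {
    do.call(rbind, lapply(parameters, function(p) {
      sp <- spearman_correlation(table, p)
      rs <- regression_slope(table, p)
      data.frame(parameter = p, R = sp$R, p = sp$p,
                 slope_per_10 = rs$slope_per_10, stringsAsFactors = FALSE)
    }))
  }
  list(summary = cs$summary, kruskal = cs$kruskal, pairwise = pw,
       correlation = corr)
}
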