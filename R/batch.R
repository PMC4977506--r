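#' Batch configuration
#'
#' Collects every knob the batch front end needs. One configuration applies
#' to all videos in the folder, making the run fully automated.
#'
#' @param input_folder Folder containing the multi-page `.tif` videos.
#' @param output_folder Where outputs are written; defaults to the input
#'   folder.
#' @param fps Frame rate shared by the videos.
#' @param arena_width_cm,arena_height_cm Arena extent in cm.
#' @param binary_threshold Binarization threshold in (0, 1); choose with
#'   [sweep_thresholds()].
#' @param invert Invert intensities (dark animal on bright arena)?
#' @param ecc_threshold,speed_threshold_cms SAP gating thresholds (see
#'   [detection_params()]).
#' @param morph_radius_cm Tail-removal disk radius in cm.
#' @param write_plots Write the three-panel per-video PNG (eccentricity,
#'   speed, SAP detection vs. time)?
#' @return A list of class `batch_config`.
#' @export
batch_config <- function(input_folder, output_folder = input_folder,
                         fps, arena_width_cm, arena_height_cm,
                         binary_threshold, invert = FALSE,
                         ecc_threshold = 0.90, speed_threshold_cms = 12,
                         morph_radius_cm = 0.25, write_plots = TRUE) {
  if (!dir.exists(input_folder)) stop("input folder does not exist")
  dir.create(output_folder, showWarnings = FALSE, recursive = TRUE)
  structure(list(input_folder = input_folder, output_folder = output_folder,
                 fps = fps, arena_width_cm = arena_width_cm,
                 arena_height_cm = arena_height_cm,
                 binary_threshold = binary_threshold, invert = invert,
                 ecc_threshold = ecc_threshold,
                 speed_threshold_cms = speed_threshold_cms,
                 morph_radius_cm = morph_radius_cm,
                 write_plots = isTRUE(write_plots)),
            class = "batch_config")
}

#' Run SAP detection over a folder of videos
#'
#' Processes every `.tif` in the input folder with a single shared
#' configuration: per video it writes `<name>_frames.csv` (frame-level
#' track and flags), `<name>_seconds.csv` (per-second flags), optionally
#' `<name>_sap.png` (three stacked panels: eccentricity, speed, SAP
#' detection vs. time), and appends one row to `summary.csv`. A failing
#' video is logged and skipped; the rest of the batch continues.
#'
#' @param config A [batch_config()].
#' @return The summary data frame (one row per processed video: `video`,
#'   `video_length_s`, `duration_s`, `sap_percent`, `positive_seconds`,
#'   `bouts`, `freq_per_min`, `n_invalid_frames`), invisibly, with a
#'   character attribute `"failures"` naming any videos that failed.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "batch_config"))
  files <- sort(list.files(config$input_folder, pattern = "\\.tiff?$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no videos found in ", config$input_folder)
  mp <- morph_params(config$binary_threshold, config$morph_radius_cm)
  dp <- detection_params(config$ecc_threshold, config$speed_threshold_cms,
                         config$fps)
  message(sprintf(
    "batch: %d video(s); fps=%g arena=%gx%g cm thr=%g ecc>%g speed<=%g cm/s",
    length(files), config$fps, config$arena_width_cm, config$arena_height_cm,
    config$binary_threshold, config$ecc_threshold,
    config$speed_threshold_cms))
  rows <- list()
  failures <- character(0)
  for (f in files) {
    nm <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch({
      video <- load_video(f, fps = config$fps,
                          arena_width_cm = config$arena_width_cm,
                          arena_height_cm = config$arena_height_cm,
                          invert = config$invert)
      track <- track_frames(video, mp)
      trace <- detect_sap(track, dp)
      frames_out <- data.frame(
        frame_index = track$frame_index, time_s = track$time_s,
        centroid_x_cm = track$centroid_x_cm,
        centroid_y_cm = track$centroid_y_cm,
        eccentricity = track$eccentricity, speed_cms = track$speed_cms,
        valid = as.integer(track$valid), sap_frame = trace$frame_flags)
      utils::write.csv(frames_out,
                       file.path(config$output_folder,
                                 paste0(nm, "_frames.csv")),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(second_index = seq_along(trace$second_flags) - 1L,
                   sap_second = trace$second_flags),
        file.path(config$output_folder, paste0(nm, "_seconds.csv")),
        row.names = FALSE)
      if (config$write_plots) {
        plot_file <- file.path(config$output_folder, paste0(nm, "_sap.png"))
        try(plot_sap_trace(track, trace, file = plot_file), silent = TRUE)
      }
      s <- summarize_sap(trace)
      cbind(data.frame(video = nm), s,
            data.frame(n_invalid_frames = sum(!track$valid)))
    }, error = function(e) {
      message("batch: '", nm, "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, nm) else {
      rows[[length(rows) + 1L]] <- res
      message(sprintf("batch: %s  SAP %.1f s (%.1f%%), %d bouts",
                      nm, res$duration_s, res$sap_percent, res$bouts))
    }
  }
  summary <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame()
  utils::write.csv(summary, file.path(config$output_folder, "summary.csv"),
                   row.names = FALSE)
  attr(summary, "failures") <- failures
  invisible(summary)
}

#' Three-panel detection plot
#'
#' Eccentricity (top), speed (middle) and the SAP detection trace (bottom,
#' shaded) against time, with the gating thresholds drawn as dashed lines.
#'
#' @param track A `sap_track`.
#' @param trace The matching `sap_trace`.
#' @param file Optional PNG path; when `NULL`, draws on the active device.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_sap_trace <- function(track, trace, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  old <- graphics::par(mfrow = c(3, 1), mar = c(4, 4.5, 1.5, 1))
  on.exit(graphics::par(old), add = TRUE)
  t <- track$time_s
  graphics::plot(t, track$eccentricity, type = "l", ylim = c(0, 1),
                 xlab = "time (s)", ylab = "eccentricity")
  graphics::abline(h = trace$params$ecc_threshold, lty = 2)
  graphics::plot(t, track$speed_cms, type = "l",
                 xlab = "time (s)", ylab = "speed (cm/s)")
  graphics::abline(h = trace$params$speed_threshold_cms, lty = 2)
  graphics::plot(t, trace$frame_flags, type = "h", ylim = c(0, 1),
                 xlab = "time (s)", ylab = "SAP detected", yaxt = "n")
  graphics::axis(2, at = c(0, 1))
  invisible(file)
}

#' Evaluate a detector per-second table against a rater panel
#'
#' Builds the majority-vote consensus from the panel, forms the confusion
#' table against the detector's per-second flags, and reports accuracy,
#' sensitivity, specificity (each with a Wald interval), F-score and MCC in
#' long format.
#'
#' @param pred Detector per-second 0/1 flags: a vector, a `sap_trace`, or a
#'   path to a `*_seconds.csv` written by [run_batch()].
#' @param panel A rater panel matrix or a path readable by
#'   [read_rater_panel()].
#' @param level Confidence level for the Wald intervals.
#' @param out Optional CSV path for the report.
#' @return Data frame with columns `metric`, `estimate`, `lower`, `upper`,
#'   `level` (interval rows only for the three proportion metrics).
#' @export
evaluate_against_panel <- function(pred, panel, level = 0.95, out = NULL) {
  if (inherits(pred, "sap_trace")) pred <- pred$second_flags
  if (is.character(pred)) pred <- utils::read.csv(pred)$sap_second
  if (is.character(panel)) panel <- read_rater_panel(panel)
  truth <- consensus(panel)
  n <- min(length(pred), length(truth))
  cc <- confusion(pred[seq_len(n)], truth[seq_len(n)])
  bm <- basic_metrics(cc)
  ci <- list(
    accuracy = wald_ci(cc$tp + cc$tn, cc$P + cc$N, level),
    sensitivity = wald_ci(cc$tp, cc$P, level),
    specificity = wald_ci(cc$tn, cc$N, level))
  report <- rbind(
    do.call(rbind, lapply(names(ci), function(m) {
      data.frame(metric = m, estimate = ci[[m]]$estimate,
                 lower = ci[[m]]$lower, upper = ci[[m]]$upper,
                 level = level)
    })),
    data.frame(metric = c("f_score", "mcc"),
               estimate = c(f_score(cc), mcc(cc)),
               lower = NA, upper = NA, level = NA))
  if (!is.null(out)) utils::write.csv(report, out, row.names = FALSE)
  report
}

#' Optimize gating thresholds on videos with per-second reference scores
#'
#' Tracks each video, sweeps the (eccentricity, speed) grid with
#' [roc_over_grid()], and returns the MCC-optimal pair together with the
#' ROC points and MCC surface.
#'
#' @param videos List of `sap_video` objects or character paths to `.tif`
#'   files.
#' @param truths List of per-second 0/1 vectors (or paths to
#'   `*_truth_seconds.csv` files), aligned with `videos`.
#' @param config A [batch_config()] supplying segmentation parameters (and
#'   loading parameters when `videos` are paths).
#' @param ecc_grid,speed_grid Candidate thresholds.
#' @param out_prefix Optional path prefix; writes `<prefix>_roc.csv` and
#'   `<prefix>_mcc_surface.csv`.
#' @return List: `optimum` (from [optimize_thresholds()]), `roc`, `auc`,
#'   `surface`.
#' @export
optimize_on_videos <- function(videos, truths, config,
                               ecc_grid = seq(0.80, 0.98, by = 0.01),
                               speed_grid = seq(4, 20, by = 1),
                               out_prefix = NULL) {
  stopifnot(inherits(config, "batch_config"))
  mp <- morph_params(config$binary_threshold, config$morph_radius_cm)
  tracks <- lapply(videos, function(v) {
    if (is.character(v)) {
      v <- load_video(v, fps = config$fps,
                      arena_width_cm = config$arena_width_cm,
                      arena_height_cm = config$arena_height_cm,
                      invert = config$invert)
    }
    track_frames(v, mp)
  })
  truths <- lapply(truths, function(tr) {
    if (is.character(tr)) utils::read.csv(tr)$sap_second else tr
  })
  rr <- roc_over_grid(tracks, truths, ecc_grid, speed_grid,
                      fps = config$fps)
  if (!is.null(out_prefix)) {
    utils::write.csv(rr$roc, paste0(out_prefix, "_roc.csv"),
                     row.names = FALSE)
    utils::write.csv(rr$surface, paste0(out_prefix, "_mcc_surface.csv"),
                     row.names = FALSE)
  }
  list(optimum = optimize_thresholds(rr), roc = rr$roc, auc = rr$auc,
       surface = rr$surface)
}
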