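#' Fit an ellipse to a binary component via image moments
#'
#' Computes the equivalent ellipse of a pixel region from its second central
#' moments: the per-pixel coordinate covariance (with the standard +1/12
#' per-pixel variance correction on both diagonal terms) is
#' eigen-decomposed; with eigenvalues \eqn{\lambda_1 \ge \lambda_2}, the
#' axis lengths are \eqn{4\sqrt{\lambda_j}} and the eccentricity is
#' \eqn{\sqrt{1 - \lambda_2/\lambda_1}}. This is the region-properties
#' convention, so an ellipse-shaped region recovers its own generating
#' ellipse. Eccentricity is the elongation proxy: 0 for a circle,
#' approaching 1 for a line segment; an elongated (stretched) animal scores
#' high.
#'
#' @param component Logical matrix holding a single non-empty connected
#'   region.
#' @return A list of class `body_ellipse`: `centroid_x_px`, `centroid_y_px`
#'   (x = 0-based column, y = 0-based row, sub-pixel), `major_axis_len_px`,
#'   `minor_axis_len_px`, `orientation_rad` (major-axis angle from the +x
#'   image axis, in (-pi/2, pi/2], y pointing down the rows), `eccentricity`
#'   and `area_px`.
#' @examples
#' m <- matrix(FALSE, 100, 100)
#' xy <- expand.grid(r = 1:100, c = 1:100)
#' el <- with(xy, ((c - 50) / 40)^2 + ((r - 50) / 10)^2 <= 1)
#' m[as.matrix(xy[el, ])] <- TRUE
#' fit_ellipse(m)$eccentricity   # close to sqrt(1 - (10/40)^2)
#' @export
fit_ellipse <- function(component) {
  stopifnot(is.logical(component), is.matrix(component))
  px <- which(component, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0L) stop("empty region: cannot fit an ellipse")
  y <- px[, 1L] - 1  # row index, 0-based
  x <- px[, 2L] - 1  # col index, 0-based
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  dy <- y - my
  mxx <- mean(dx * dx) + 1 / 12
  myy <- mean(dy * dy) + 1 / 12
  mxy <- mean(dx * dy)
  # eigenvalues of [[mxx, mxy], [mxy, myy]]
  tr <- mxx + myy
  disc <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  structure(
    list(centroid_x_px = mx, centroid_y_px = my,
         major_axis_len_px = 4 * sqrt(l1),
         minor_axis_len_px = 4 * sqrt(l2),
         orientation_rad = theta,
         eccentricity = sqrt(max(0, 1 - l2 / l1)),
         area_px = n),
    class = "body_ellipse")
}

#' Segmentation parameters for tracking
#'
#' @param binary_threshold Binarization threshold in (0, 1) applied to the
#'   background-subtracted frame; choose with [sweep_thresholds()]. No
#'   universal default exists -- it depends on lighting and contrast -- so it
#'   must be set explicitly.
#' @param morph_radius_cm Radius of the disk structuring element used by the
#'   tail-removal opening, in cm (default 0.25 cm; at least 1 px after
#'   conversion). Should exceed the tail half-width but stay well below the
#'   body half-width.
#' @return A list of class `morph_params`.
#' @export
morph_params <- function(binary_threshold, morph_radius_cm = 0.25) {
  stopifnot(binary_threshold > 0, binary_threshold < 1, morph_radius_cm >= 0)
  structure(list(binary_threshold = binary_threshold,
                 morph_radius_cm = morph_radius_cm),
            class = "morph_params")
}

#' Segment and track the animal across all frames
#'
#' Runs the per-frame pipeline (binarize by background subtraction, remove
#' the tail by opening, keep the largest component, fit the moment ellipse)
#' and derives the centroid speed. The speed assigned to frame *i* is the
#' Euclidean centroid displacement from frame *i - 1*, converted to cm and
#' multiplied by the frame rate; the first valid frame gets speed 0, and a
#' frame following an invalid (animal-absent) gap restarts at speed 0 --
#' a still animal reappearing is not speed-vetoed.
#'
#' @param video A `sap_video` from [load_video()] or [render_scenario()].
#' @param params A [morph_params()] object.
#' @return A `data.frame` of class `sap_track`, one row per frame:
#'   `frame_index`, `time_s`, `centroid_x_px`, `centroid_y_px`,
#'   `centroid_x_cm`, `centroid_y_cm`, `major_axis_len_px`,
#'   `minor_axis_len_px`, `orientation_rad`, `eccentricity`, `area_px`,
#'   `speed_cms`, `valid`. Attributes `fps` and `cm_per_px` carry the
#'   calibration.
#' @export
track_frames <- function(video, params) {
  stopifnot(inherits(video, "sap_video"), inherits(params, "morph_params"))
  radius_px <- if (params$morph_radius_cm == 0) 0L else
    max(1L, as.integer(round(params$morph_radius_cm / video$cm_per_px)))
  n <- length(video$frames)
  cols <- c("centroid_x_px", "centroid_y_px", "major_axis_len_px",
            "minor_axis_len_px", "orientation_rad", "eccentricity",
            "area_px")
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  valid <- logical(n)
  for (i in seq_len(n)) {
    m <- binarize_frame(video$frames[[i]], video$background,
                        params$binary_threshold)
    m <- remove_tail(m, radius_px)
    comp <- largest_component(m)
    if (!attr(comp, "empty")) {
      e <- fit_ellipse(comp)
      out[i, ] <- c(e$centroid_x_px, e$centroid_y_px, e$major_axis_len_px,
                    e$minor_axis_len_px, e$orientation_rad, e$eccentricity,
                    e$area_px)
      valid[i] <- TRUE
    }
  }
  if (!any(valid)) stop("no animal detected in video")
  speed <- numeric(n)
  for (i in seq_len(n)[-1L]) {
    if (valid[i] && valid[i - 1L]) {
      d <- sqrt((out[i, 1L] - out[i - 1L, 1L])^2 +
                (out[i, 2L] - out[i - 1L, 2L])^2)
      speed[i] <- d * video$cm_per_px * video$fps
    }
  }
  track <- data.frame(frame_index = seq_len(n),
                      time_s = (seq_len(n) - 1L) / video$fps,
                      out,
                      centroid_x_cm = out[, "centroid_x_px"] * video$cm_per_px,
                      centroid_y_cm = out[, "centroid_y_px"] * video$cm_per_px,
                      speed_cms = speed,
                      valid = valid)
  class(track) <- c("sap_track", "data.frame")
  attr(track, "fps") <- video$fps
  attr(track, "cm_per_px") <- video$cm_per_px
  track
}

#' SAP gating thresholds
#'
#' Defaults are for an open-field arena with adult mice: eccentricity above
#' 0.90 marks elongation and speed above 12 cm/s vetoes running. For an
#' elevated plus maze, where the animal bends toward the open arms and has
#' less room to accelerate, 0.89 and 8 cm/s are appropriate
#' (`detection_params(0.89, 8, fps)`). Thresholds are strain-, sex- and
#' weight-specific; re-derive them for other animals with
#' [optimize_thresholds()].
#'
#' @param ecc_threshold Eccentricity threshold in \[0, 1): a frame is
#'   elongated when eccentricity is strictly greater.
#' @param speed_threshold_cms Speed veto in cm/s (> 0): a frame is vetoed
#'   when speed is strictly greater.
#' @param fps Frame rate, needed by the bout filter and the per-second
#'   aggregation.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(ecc_threshold = 0.90, speed_threshold_cms = 12,
                             fps = 10) {
  stopifnot(ecc_threshold >= 0, ecc_threshold < 1, speed_threshold_cms > 0,
            fps > 0)
  structure(list(ecc_threshold = ecc_threshold,
                 speed_threshold_cms = speed_threshold_cms, fps = fps),
            class = "detection_params")
}

#' Zero out short runs of positive frames
#'
#' SAP is assumed never to last half a second or less; any maximal run of 1s
#' of length `<= max_len` frames is set to 0 to suppress false positives
#' from transient elongation. With `max_len = round(fps / 2)` this is the
#' built-in half-second filter.
#'
#' @param flags Integer/numeric vector of 0s and 1s.
#' @param max_len Maximum run length (in frames) to erase.
#' @return The filtered 0/1 integer vector; idempotent, never creates 1s.
#' @export
filter_short_bouts <- function(flags, max_len) {
  stopifnot(all(flags %in% c(0, 1)), max_len >= 0)
  if (length(flags) == 0L || max_len == 0) return(as.integer(flags))
  r <- rle(as.integer(flags))
  r$values[r$values == 1L & r$lengths <= max_len] <- 0L
  inverse.rle(r)
}

# second_index (0-based) for each frame at the given fps
frame_seconds <- function(n_frames, fps) {
  floor((seq_len(n_frames) - 1L) / fps)
}

#' Detect stretch-attend posture from a frame track
#'
#' A frame is SAP-positive when the animal is present, its ellipse
#' eccentricity strictly exceeds `ecc_threshold` (elongated) and its speed
#' does not strictly exceed `speed_threshold_cms` (not running). Runs of
#' positives no longer than `round(fps/2)` frames are then erased (the
#' half-second minimum-bout filter), and per-second flags are derived by the
#' at-least-one-frame rule: a second is positive iff any of its frames is.
#' A trailing partial second, if the frame count is not a multiple of `fps`,
#' is aggregated the same way.
#'
#' @param track A `sap_track` from [track_frames()], or any data frame with
#'   columns `eccentricity`, `speed_cms`, `valid`.
#' @param params A [detection_params()] object.
#' @return A list of class `sap_trace`: `frame_flags` (0/1 per frame),
#'   `second_flags` (0/1 per second), `n_frames`, `fps`, `params`.
#' @export
detect_sap <- function(track, params) {
  stopifnot(inherits(params, "detection_params"))
  n <- nrow(track)
  if (is.null(n) || n == 0L) stop("no frames in track")
  ecc <- track$eccentricity
  speed <- track$speed_cms
  valid <- track$valid
  flags <- as.integer(valid & !is.na(ecc) &
                        ecc > params$ecc_threshold &
                        !(speed > params$speed_threshold_cms))
  flags <- filter_short_bouts(flags, round(params$fps / 2))
  sec <- frame_seconds(n, params$fps)
  second_flags <- as.integer(rowsum(flags, sec)[, 1L] > 0)
  structure(list(frame_flags = flags,
                 second_flags = second_flags,
                 n_frames = n, fps = params$fps, params = params),
            class = "sap_trace")
}

#' @export
print.sap_trace <- function(x, ...) {
  cat(sprintf(
    "<sap_trace> %d frames @ %g fps: %d SAP frames, %d/%d SAP seconds\n",
    x$n_frames, x$fps, sum(x$frame_flags), sum(x$second_flags),
    length(x$second_flags)))
  invisible(x)
}

#' Per-video SAP summary
#'
#' Duration is frame-based (SAP frames / fps, the canonical definition
#' here); the positive-second count is also reported since per-second
#' scoring is what rater panels produce. A bout is a maximal run of
#' SAP-positive frames; the frequency is bouts per minute of video.
#'
#' @param trace A `sap_trace` from [detect_sap()].
#' @return One-row `data.frame`: `video_length_s`, `duration_s`,
#'   `sap_percent`, `positive_seconds`, `bouts`, `freq_per_min`.
#' @export
summarize_sap <- function(trace) {
  stopifnot(inherits(trace, "sap_trace"))
  len_s <- trace$n_frames / trace$fps
  r <- rle(trace$frame_flags)
  bouts <- sum(r$values == 1L)
  duration_s <- sum(trace$frame_flags) / trace$fps
  data.frame(video_length_s = len_s,
             duration_s = duration_s,
             sap_percent = 100 * duration_s / len_s,
             positive_seconds = sum(trace$second_flags),
             bouts = bouts,
             freq_per_min = bouts / (len_s / 60))
}
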