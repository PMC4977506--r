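#' Load an overhead rodent video from a multi-page TIFF
#'
#' Reads a grayscale multi-page TIFF in which every page but the last is a
#' video frame and the last page is an image of the empty arena, used for
#' background subtraction. Pixel intensities are normalized to \[0, 1\]
#' (integer pixel types are rescaled by their type maximum). RGB pages are
#' collapsed to grayscale by channel mean.
#'
#' @param path Path to a readable multi-page TIFF with at least 2 pages.
#' @param fps Frame rate of the recording, frames per second (> 0).
#' @param arena_width_cm,arena_height_cm Physical extent of the (cropped)
#'   field of view in cm. The crop is assumed square-pixel: the per-axis
#'   cm/px implied by width and height must agree within 2\%.
#' @param invert If `TRUE`, every intensity `v` becomes `1 - v` in frames and
#'   background. Use for dark animals on a bright arena; detection assumes a
#'   bright animal after (optional) inversion.
#' @param background_path Optional path to a separate single-page TIFF to use
#'   as the background instead of the last page. When supplied, *all* pages
#'   of `path` are treated as frames.
#'
#' @return A `sap_video` object: a list with `frames` (list of numeric
#'   matrices in \[0,1\], rows = image y, columns = image x), `background`
#'   (one such matrix), `fps`, `arena_width_cm`, `arena_height_cm` and the
#'   derived calibration `cm_per_px = arena_width_cm / width_px`.
#'
#' @examples
#' v <- render_scenario(synth_scenario(n_frames = 5))$video
#' p <- file.path(tempdir(), "demo.tif")
#' write_video(v, p)
#' v2 <- load_video(p, fps = v$fps, arena_width_cm = 30, arena_height_cm = 30)
#' length(v2$frames)
#' @seealso [write_video()], [sweep_thresholds()], [track_frames()]
#' @export
load_video <- function(path, fps, arena_width_cm, arena_height_cm,
                       invert = FALSE, background_path = NULL) {
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0,
            is.numeric(arena_width_cm), arena_width_cm > 0,
            is.numeric(arena_height_cm), arena_height_cm > 0)
  if (!file.exists(path)) {
    stop("cannot read video file: ", path)
  }
  pages <- lapply(tiff::readTIFF(path, all = TRUE), as_gray_matrix)
  if (is.null(background_path)) {
    if (length(pages) < 2L) {
      stop("no background frame: the TIFF has fewer than 2 pages ",
           "(the last page must be the empty-arena background)")
    }
    frames <- pages[-length(pages)]
    background <- pages[[length(pages)]]
  } else {
    bg_pages <- lapply(tiff::readTIFF(background_path, all = TRUE),
                       as_gray_matrix)
    frames <- pages
    background <- bg_pages[[1L]]
  }
  dims <- vapply(c(frames, list(background)), dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("ragged stack: pages have inconsistent dimensions")
  }
  if (invert) {
    frames <- lapply(frames, function(f) 1 - f)
    background <- 1 - background
  }
  new_sap_video(frames, background, fps, arena_width_cm, arena_height_cm)
}

# Collapse a readTIFF page to a 2-D grayscale matrix in [0,1].
as_gray_matrix <- function(page) {
  if (length(dim(page)) == 3L) {
    page <- apply(page, c(1L, 2L), mean)
  }
  storage.mode(page) <- "double"
  page
}

new_sap_video <- function(frames, background, fps,
                          arena_width_cm, arena_height_cm) {
  h <- nrow(background)
  w <- ncol(background)
  if (h < 8L || w < 8L) stop("frames must be at least 8x8 pixels")
  if (length(frames) < 1L) stop("video has no frames")
  cmppx_w <- arena_width_cm / w
  cmppx_h <- arena_height_cm / h
  if (abs(cmppx_w - cmppx_h) / cmppx_w > 0.02) {
    stop("square-pixel check failed: width implies ",
         signif(cmppx_w, 4), " cm/px but height implies ",
         signif(cmppx_h, 4), " cm/px (must agree within 2%); ",
         "crop the video to the arena with a 1:1 aspect ratio")
  }
  structure(
    list(frames = frames, background = background, fps = fps,
         arena_width_cm = arena_width_cm, arena_height_cm = arena_height_cm,
         cm_per_px = cmppx_w),
    class = "sap_video")
}

#' @export
print.sap_video <- function(x, ...) {
  cat(sprintf(
    "<sap_video> %d frames of %dx%d px + background, %g fps, %g x %g cm (%.4g cm/px)\n",
    length(x$frames), nrow(x$background), ncol(x$background),
    x$fps, x$arena_width_cm, x$arena_height_cm, x$cm_per_px))
  invisible(x)
}

#' Write a video back to a multi-page TIFF
#'
#' Writes the frames followed by the background as the last page, the layout
#' [load_video()] reads. Round-tripping reproduces intensities within the
#' output quantization (1/255 for 8-bit, 1/65535 for 16-bit).
#'
#' @param video A `sap_video` object.
#' @param path Output file path (`.tif`).
#' @param bits_per_sample Output bit depth, 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path, bits_per_sample = 8L) {
  stopifnot(inherits(video, "sap_video"), bits_per_sample %in% c(8L, 16L))
  pages <- c(video$frames, list(video$background))
  pages <- lapply(pages, function(p) pmin(pmax(p, 0), 1))
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits_per_sample)),
    error = function(e) stop("cannot write video file '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}

#' Headless binary-threshold previewer
#'
#' Replaces an interactive threshold preview with a deterministic sweep: for
#' each candidate threshold the background-subtracted sample frame
#' (`pmax(frame - background, 0)`) is binarized and the fraction of
#' foreground pixels recorded. A suitable threshold sits on the plateau where
#' the fraction matches the expected animal size; too low floods the arena
#' floor, too high erodes the animal away.
#'
#' @param video A `sap_video` object.
#' @param thresholds Numeric vector of candidate thresholds, all in (0, 1).
#' @param frame_index Index of the sample frame to sweep (default 1).
#' @return A `data.frame` of class `threshold_sweep` with columns
#'   `threshold` (ascending) and `foreground_fraction` (non-increasing).
#' @examples
#' v <- render_scenario(synth_scenario(n_frames = 3))$video
#' sweep_thresholds(v, thresholds = c(0.2, 0.4, 0.6))
#' @export
sweep_thresholds <- function(video, thresholds, frame_index = 1L) {
  stopifnot(inherits(video, "sap_video"))
  if (length(thresholds) == 0L) stop("no thresholds supplied")
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  if (frame_index < 1L || frame_index > length(video$frames)) {
    stop("frame_index out of range")
  }
  d <- pmax(video$frames[[frame_index]] - video$background, 0)
  thr <- sort(thresholds)
  frac <- vapply(thr, function(t) mean(d > t), numeric(1L))
  structure(data.frame(threshold = thr, foreground_fraction = frac),
            class = c("threshold_sweep", "data.frame"))
}
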