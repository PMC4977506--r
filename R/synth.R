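#' Define a synthetic overhead-video scenario
#'
#' Describes a calibrated synthetic video of a single bright, elongate
#' "mouse" on a dark arena floor: per-frame body semi-axes, heading and
#' centroid trajectory, an optional attached tapering tail, an optional
#' floor grid pattern, and additive Gaussian intensity noise. Scalar
#' schedule arguments are recycled to `n_frames`. Rendering (see
#' [render_scenario()]) follows the same conventions the loader expects:
#' grayscale in \[0, 1\], empty-arena background as the last TIFF page.
#'
#' Defaults emulate an open-field recording: a 30 cm square arena imaged at
#' 150 px (0.2 cm/px), 10 frames/s, and a body of an adult ~35 g mouse
#' (elongated length ~7 cm when `a_cm = 3.5`). The tail defaults (3 cm
#' long, 0.4 cm at the root, tapering) are chosen to stress the
#' morphological tail removal without touching the body.
#'
#' @param arena_width_cm,arena_height_cm Arena extent in cm (default 30 x 30).
#' @param width_px Frame width in pixels; height follows from the arena
#'   aspect ratio.
#' @param fps Frames per second.
#' @param n_frames Number of animal frames (the background page is extra).
#' @param a_cm,b_cm Body semi-major/semi-minor axes in cm, scalars or
#'   per-frame vectors; `a_cm >= b_cm > 0`.
#' @param heading_rad Body heading (major-axis angle), scalar or per-frame.
#' @param x_cm,y_cm Centroid trajectory in cm; defaults to the arena
#'   center, stationary. Must stay at least `a_cm` from every arena edge.
#' @param tail Render the tail? (logical)
#' @param tail_length_cm,tail_width_cm Tail length and root width in cm.
#' @param background_level,grid_level,body_level Intensities in \[0, 1\];
#'   `body_level > background_level`.
#' @param grid_on Draw a 4 x 4 floor grid (painted lines at `grid_level`)?
#' @param noise_sd Standard deviation of additive Gaussian pixel noise on
#'   the animal frames (the background page stays noise-free).
#' @param ecc_threshold,speed_threshold_cms Gating thresholds used to derive
#'   the analytic ground-truth SAP labels.
#' @param seed Integer seed making the rendering bit-reproducible.
#' @return A list of class `synth_scenario`.
#' @export
synth_scenario <- function(arena_width_cm = 30, arena_height_cm = 30,
                           width_px = 150L, fps = 10, n_frames = 50L,
                           a_cm = 3.5, b_cm = 1.1, heading_rad = 0,
                           x_cm = NULL, y_cm = NULL,
                           tail = TRUE, tail_length_cm = 3,
                           tail_width_cm = 0.4,
                           background_level = 0.10, grid_level = 0.30,
                           grid_on = TRUE, body_level = 0.85,
                           noise_sd = 0,
                           ecc_threshold = 0.90, speed_threshold_cms = 12,
                           seed = 1L) {
  n <- as.integer(n_frames)
  stopifnot(n >= 1L, fps > 0, width_px >= 8L,
            body_level > background_level, noise_sd >= 0)
  rec <- function(v) rep_len(v, n)
  a <- rec(a_cm); b <- rec(b_cm); th <- rec(heading_rad)
  if (any(b <= 0) || any(a < b)) stop("need a_cm >= b_cm > 0 per frame")
  if (is.null(x_cm)) x_cm <- arena_width_cm / 2
  if (is.null(y_cm)) y_cm <- arena_height_cm / 2
  x <- rec(x_cm); y <- rec(y_cm)
  if (any(x < a) || any(x > arena_width_cm - a) ||
      any(y < a) || any(y > arena_height_cm - a)) {
    stop("trajectory out of bounds: the body must stay at least a_cm from ",
         "every arena edge")
  }
  structure(list(arena_width_cm = arena_width_cm,
                 arena_height_cm = arena_height_cm,
                 width_px = as.integer(width_px), fps = fps, n_frames = n,
                 a_cm = a, b_cm = b, heading_rad = th, x_cm = x, y_cm = y,
                 tail = isTRUE(tail), tail_length_cm = tail_length_cm,
                 tail_width_cm = tail_width_cm,
                 background_level = background_level,
                 grid_level = grid_level, grid_on = isTRUE(grid_on),
                 body_level = body_level, noise_sd = noise_sd,
                 ecc_threshold = ecc_threshold,
                 speed_threshold_cms = speed_threshold_cms,
                 seed = as.integer(seed)),
            class = "synth_scenario")
}

#' Render a scenario into a video plus analytic ground truth
#'
#' Each frame paints the filled body ellipse (rotated to its heading) and,
#' if enabled, a tapering quadratically-curled tail attached at the rear
#' vertex, over the arena background; seeded Gaussian noise is then added
#' and clamped to \[0, 1\]. The last page is the noise-free, animal-free
#' background.
#'
#' Ground truth is computed from the schedules, never from the rendered
#' pixels: per-frame eccentricity is the analytic
#' \eqn{\sqrt{1 - (b/a)^2}}, speed comes from the trajectory differences,
#' and the SAP labels apply the standard gating (eccentricity strictly
#' above threshold, speed veto, half-second bout filter, at-least-one-frame
#' second rule) to those analytic traces at the scenario's thresholds.
#' Rendering changes therefore cannot silently shift the labels.
#'
#' @param s A [synth_scenario()].
#' @return A list with `video` (a `sap_video`), `truth` (list of data
#'   frames `frame`: `frame_index`, `eccentricity`, `speed_cms`,
#'   `sap_frame`; and `second`: `second_index`, `sap_second`) and
#'   `scenario`.
#' @examples
#' out <- render_scenario(synth_scenario(n_frames = 10))
#' out$truth$second
#' @export
render_scenario <- function(s) {
  stopifnot(inherits(s, "synth_scenario"))
  cmpp <- s$arena_width_cm / s$width_px
  h <- as.integer(round(s$arena_height_cm / cmpp))
  w <- s$width_px
  # pixel-center coordinates in cm
  xs <- (seq_len(w) - 0.5) * cmpp
  ys <- (seq_len(h) - 0.5) * cmpp
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)

  background <- matrix(s$background_level, h, w)
  if (s$grid_on) {
    lines_px <- round(seq_len(3) * w / 4)
    background[, lines_px] <- s$grid_level
    background[round(seq_len(3) * h / 4), ] <- s$grid_level
  }

  frames <- withr::with_seed(s$seed, lapply(seq_len(s$n_frames), function(i) {
    f <- background
    body <- body_mask(X, Y, s$x_cm[i], s$y_cm[i], s$a_cm[i], s$b_cm[i],
                      s$heading_rad[i])
    f[body] <- s$body_level
    if (s$tail) {
      f[tail_mask(X, Y, s$x_cm[i], s$y_cm[i], s$a_cm[i], s$heading_rad[i],
                  s$tail_length_cm, s$tail_width_cm, cmpp)] <- s$body_level
    }
    if (s$noise_sd > 0) {
      f <- pmin(pmax(f + matrix(stats::rnorm(h * w, 0, s$noise_sd), h, w),
                     0), 1)
    }
    f
  }))

  video <- new_sap_video(frames, background, s$fps,
                         s$arena_width_cm, s$arena_height_cm)

  ecc <- sqrt(1 - (s$b_cm / s$a_cm)^2)
  speed <- c(0, sqrt(diff(s$x_cm)^2 + diff(s$y_cm)^2) * s$fps)
  analytic <- data.frame(eccentricity = ecc, speed_cms = speed,
                         valid = TRUE)
  trace <- detect_sap(analytic,
                      detection_params(s$ecc_threshold,
                                       s$speed_threshold_cms, s$fps))
  truth <- list(
    frame = data.frame(frame_index = seq_len(s$n_frames),
                       eccentricity = ecc, speed_cms = speed,
                       sap_frame = trace$frame_flags),
    second = data.frame(second_index = seq_along(trace$second_flags) - 1L,
                        sap_second = trace$second_flags))
  list(video = video, truth = truth, scenario = s)
}

# filled rotated ellipse over cm-coordinate pixel grids
body_mask <- function(X, Y, cx, cy, a, b, theta) {
  dx <- X - cx
  dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# tapering tail: quadratic polyline leaving the rear vertex, as a union of
# stamped disks along sampled curve points
tail_mask <- function(X, Y, cx, cy, a, theta, length_cm, width_cm, cmpp) {
  d <- c(-cos(theta), -sin(theta))      # backward along the major axis
  p <- c(-sin(theta), cos(theta))       # perpendicular (lateral curl)
  # rear vertex, inset by half the root width so the tail overlaps the body
  root <- c(cx, cy) - (a - width_cm / 2) * c(cos(theta), sin(theta))
  t <- seq(0, 1, length.out = 40L)
  px <- root[1L] + d[1L] * length_cm * t + p[1L] * 0.3 * length_cm * t^2
  py <- root[2L] + d[2L] * length_cm * t + p[2L] * 0.3 * length_cm * t^2
  radius <- pmax(width_cm * (1 - 0.8 * t) / 2, 0.6 * cmpp)
  mask <- matrix(FALSE, nrow(X), ncol(X))
  # restrict work to the tail's bounding box
  rmax <- max(radius)
  rows <- which(Y[, 1L] >= min(py) - rmax & Y[, 1L] <= max(py) + rmax)
  cols <- which(X[1L, ] >= min(px) - rmax & X[1L, ] <= max(px) + rmax)
  if (length(rows) == 0L || length(cols) == 0L) return(mask)
  subX <- X[rows, cols, drop = FALSE]
  subY <- Y[rows, cols, drop = FALSE]
  sub <- matrix(FALSE, length(rows), length(cols))
  for (k in seq_along(t)) {
    sub <- sub | ((subX - px[k])^2 + (subY - py[k])^2 <= radius[k]^2)
  }
  mask[rows, cols] <- sub
  mask
}

#' Render the standard battery of test scenarios
#'
#' A deterministic set of seven open-field-like scenarios (30 cm square
#' arena, 10 fps, 150 px frames) spanning the behavioral regimes the
#' detector must separate:
#' \enumerate{
#'   \item `still_round` -- compact body, stationary: never SAP.
#'   \item `still_sap` -- elongated body (eccentricity 0.949), stationary,
#'     tail on: SAP throughout.
#'   \item `fast_elongated` -- elongated body orbiting at 20 cm/s: vetoed.
#'   \item `brief_elongation` -- a 0.3 s elongation burst: erased by the
#'     half-second bout filter.
#'   \item `mixed` -- 12 s alternating all regimes on whole-second
#'     boundaries.
#'   \item `still_sap_no_tail` -- tail-free twin of `still_sap`, isolating
#'     the tail-removal stage.
#'   \item `noisy_mixed` -- the `mixed` schedule with `noise_sd = 0.05`.
#' }
#'
#' @param seed Integer master seed; each scenario derives its own sub-seed,
#'   and the same seed yields bit-identical videos.
#' @return Named list; each element has `video`, `truth`, `scenario` (see
#'   [render_scenario()]).
#' @export
standard_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  round_a <- 1.8; round_b <- 1.8
  elong_a <- 3.5; elong_b <- 1.1
  orbit <- function(n, speed_cms, fps = 10, r = 4, home = c(15, 15)) {
    # circle through `home`, centered r to the left; exact chord = speed/fps
    step <- speed_cms / fps
    omega <- 2 * asin(step / (2 * r))
    phi <- (seq_len(n) - 1L) * omega
    list(x = home[1L] - r + r * cos(phi), y = home[2L] + r * sin(phi))
  }
  mixed_sched <- function() {
    n <- 120L
    a <- rep(round_a, n); b <- rep(round_b, n)
    x <- rep(15, n); y <- rep(15, n)
    elong <- c(21:50, 51:70, 91:120)
    a[elong] <- elong_a; b[elong] <- elong_b
    o <- orbit(20L, 20)
    x[51:70] <- o$x; y[51:70] <- o$y
    list(n = n, a = a, b = b, x = x, y = y)
  }
  m <- mixed_sched()
  defs <- list(
    still_round = list(a_cm = round_a, b_cm = round_b, n_frames = 50L),
    still_sap = list(a_cm = elong_a, b_cm = elong_b, n_frames = 50L),
    fast_elongated = {
      o <- orbit(50L, 20)
      list(a_cm = elong_a, b_cm = elong_b, n_frames = 50L,
           x_cm = o$x, y_cm = o$y)
    },
    brief_elongation = {
      a <- rep(round_a, 50L); b <- rep(round_b, 50L)
      a[21:23] <- elong_a; b[21:23] <- elong_b
      list(a_cm = a, b_cm = b, n_frames = 50L)
    },
    mixed = list(a_cm = m$a, b_cm = m$b, x_cm = m$x, y_cm = m$y,
                 n_frames = m$n),
    still_sap_no_tail = list(a_cm = elong_a, b_cm = elong_b, n_frames = 50L,
                             tail = FALSE),
    noisy_mixed = list(a_cm = m$a, b_cm = m$b, x_cm = m$x, y_cm = m$y,
                       n_frames = m$n, noise_sd = 0.05)
  )
  out <- lapply(seq_along(defs), function(i) {
    args <- c(defs[[i]], list(seed = seed * 100L + i))
    render_scenario(do.call(synth_scenario, args))
  })
  names(out) <- names(defs)
  out
}

#' Write a rendered suite to disk as TIFFs plus ground-truth tables
#'
#' Materializes synthetic fixtures: one multi-page TIFF per scenario (frames
#' then background, the loader's convention) and two CSVs with the analytic
#' per-frame and per-second ground truth.
#'
#' @param suite Output of [standard_suite()] (or any named list of
#'   [render_scenario()] results).
#' @param out_dir Output directory, created if needed.
#' @return Data frame listing the files written, invisibly.
#' @export
write_suite <- function(suite, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(suite), function(nm) {
    v <- file.path(out_dir, paste0(nm, ".tif"))
    write_video(suite[[nm]]$video, v)
    ft <- file.path(out_dir, paste0(nm, "_truth_frames.csv"))
    st <- file.path(out_dir, paste0(nm, "_truth_seconds.csv"))
    utils::write.csv(suite[[nm]]$truth$frame, ft, row.names = FALSE)
    utils::write.csv(suite[[nm]]$truth$second, st, row.names = FALSE)
    data.frame(scenario = nm, video = v, truth_frames = ft,
               truth_seconds = st)
  })
  invisible(do.call(rbind, rows))
}
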