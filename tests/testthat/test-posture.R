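test_that("moment ellipse recovers analytic shapes", {
  # circle: eccentricity ~ 0
  disk <- ellipse_mask(60, 20, 20)
  expect_lte(fit_ellipse(disk)$eccentricity, 0.02)

  # axis-aligned 40 x 10 ellipse
  e <- fit_ellipse(ellipse_mask(100, 40, 10))
  expect_equal(e$eccentricity, sqrt(1 - (10 / 40)^2), tolerance = 0.02)
  expect_equal(abs(e$orientation_rad), 0, tolerance = 3 * pi / 180)
  expect_equal(e$major_axis_len_px, 80, tolerance = 2)
  expect_equal(e$minor_axis_len_px, 20, tolerance = 1)

  # the same shape rotated 37 degrees: invariant eccentricity, recovered
  # orientation
  th <- 37 * pi / 180
  er <- fit_ellipse(ellipse_mask(110, 40, 10, theta = th))
  expect_equal(er$eccentricity, e$eccentricity, tolerance = 0.02)
  expect_equal(er$orientation_rad, th, tolerance = 3 * pi / 180)

  expect_error(fit_ellipse(matrix(FALSE, 5, 5)), "empty region")
})

test_that("implementation matches brute-force moment summation", {
  set.seed(3)
  for (i in 1:5) {
    a <- runif(1, 20, 40)
    b <- runif(1, 8, a)
    th <- runif(1, -pi / 2, pi / 2)
    m <- ellipse_mask(110, a, b, theta = th)
    expect_equal(fit_ellipse(m)$eccentricity, brute_moment_ecc(m),
                 tolerance = 1e-9)
  }
})

test_that("eccentricity is invariant under rigid motion of the shape", {
  base <- fit_ellipse(ellipse_mask(130, 30, 12))$eccentricity
  for (th in c(0.3, 1.1, -0.7)) {
    moved <- ellipse_mask(130, 30, 12, theta = th, cx = 70.3, cy = 55.8)
    expect_equal(fit_ellipse(moved)$eccentricity, base, tolerance = 0.02)
  }
})

make_translating_video <- function(steps_px, blob_h = 11, blob_w = 7,
                                   n_px = 100) {
  bg <- matrix(0.05, n_px, n_px)
  pages <- lapply(cumsum(c(20, steps_px)), function(x0) {
    f <- bg
    f[45:(45 + blob_h - 1), x0:(x0 + blob_w - 1)] <- 0.9
    f
  })
  p <- write_pages(c(pages, list(bg)))
  load_video(p, fps = 10, arena_width_cm = 30, arena_height_cm = 30)
}

test_that("speed is displacement times calibration times fps", {
  # 4 px/frame at 0.3 cm/px and 10 fps -> 12 cm/s after the first frame
  v <- make_translating_video(rep(4, 5))
  tr <- track_frames(v, morph_params(0.4, morph_radius_cm = 0))
  expect_equal(tr$speed_cms, c(0, rep(4 * 0.3 * 10, 5)), tolerance = 1e-9)

  # stationary: all zero
  v0 <- make_translating_video(rep(0, 3))
  tr0 <- track_frames(v0, morph_params(0.4, morph_radius_cm = 0))
  expect_equal(tr0$speed_cms, rep(0, 4))

  # doubling the displacement doubles the speed exactly
  v2 <- make_translating_video(rep(8, 5))
  tr2 <- track_frames(v2, morph_params(0.4, morph_radius_cm = 0))
  expect_equal(tr2$speed_cms[-1], 2 * tr$speed_cms[-1], tolerance = 1e-12)
})

test_that("an animal-free frame is invalid and restarts speed at zero", {
  bg <- matrix(0.05, 100, 100)
  blob <- function(x0) { f <- bg; f[45:55, x0:(x0 + 6)] <- 0.9; f }
  p <- write_pages(list(blob(20), blob(24), bg, blob(32), blob(36), bg))
  v <- load_video(p, 10, 30, 30)
  tr <- track_frames(v, morph_params(0.4, morph_radius_cm = 0))
  expect_equal(tr$valid, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(tr$speed_cms[2], 4 * 0.3 * 10, tolerance = 1e-9)
  expect_equal(tr$speed_cms[3], 0)  # invalid frame
  expect_equal(tr$speed_cms[4], 0)  # post-gap restart
  expect_equal(tr$speed_cms[5], 4 * 0.3 * 10, tolerance = 1e-9)

  # all-background video: no animal at all
  pb <- write_pages(list(bg, bg, bg))
  vb <- load_video(pb, 10, 30, 30)
  expect_error(track_frames(vb, morph_params(0.4)), "no animal detected")
})

fake_track <- function(ecc, speed = 0, valid = TRUE) {
  n <- max(length(ecc), length(speed))
  data.frame(eccentricity = rep_len(ecc, n), speed_cms = rep_len(speed, n),
             valid = rep_len(valid, n))
}

test_that("gating: elongated and slow is SAP, fast or round is not", {
  dp <- detection_params(0.90, 12, 10)
  t1 <- detect_sap(fake_track(rep(0.95, 30)), dp)
  expect_equal(t1$frame_flags, rep(1L, 30))
  expect_equal(t1$second_flags, c(1L, 1L, 1L))

  expect_equal(detect_sap(fake_track(rep(0.95, 30), speed = 20), dp)$frame_flags,
               rep(0L, 30))
  expect_equal(detect_sap(fake_track(rep(0.85, 30)), dp)$frame_flags,
               rep(0L, 30))
  # boundary comparisons are strict
  expect_equal(detect_sap(fake_track(rep(0.90, 30)), dp)$frame_flags,
               rep(0L, 30))
  expect_equal(sum(detect_sap(fake_track(rep(0.95, 30), speed = 12),
                              dp)$frame_flags), 30)
})

test_that("the half-second bout filter erases runs up to round(fps/2)", {
  dp <- detection_params(0.90, 12, 10)
  five <- c(rep(0, 3), rep(0.95, 5), rep(0, 22))
  expect_equal(sum(detect_sap(fake_track(ifelse(five > 0, five, 0.5)),
                              dp)$frame_flags), 0)
  six <- c(rep(0.5, 3), rep(0.95, 6), rep(0.5, 21))
  expect_equal(sum(detect_sap(fake_track(six), dp)$frame_flags), 6)

  # invalid frames break runs: at 8 fps runs of 4 are filtered, so a
  # 4 + gap + 4 pattern vanishes while an unbroken 9 survives
  ecc <- rep(0.95, 9)
  valid <- c(rep(TRUE, 4), FALSE, rep(TRUE, 4))
  dp8 <- detection_params(0.90, 12, 8)
  expect_equal(sum(detect_sap(fake_track(ecc, valid = valid),
                              dp8)$frame_flags), 0)
  expect_equal(sum(detect_sap(fake_track(ecc), dp8)$frame_flags), 9)
})

test_that("bout filter properties hold on random strings", {
  set.seed(5)
  for (i in 1:50) {
    flags <- rbinom(40, 1, 0.5)
    out <- filter_short_bouts(flags, 5)
    r <- rle(out)
    expect_false(any(r$values == 1 & r$lengths <= 5))
    expect_identical(filter_short_bouts(out, 5), out)   # idempotent
    expect_true(all(out <= flags))                      # never creates 1s
  }
})

test_that("per-second aggregation uses the at-least-one-frame rule", {
  dp <- detection_params(0.90, 12, 10)
  ecc <- rep(0.5, 35)
  ecc[11:17] <- 0.95      # 7-frame run inside seconds 1 (frames 11-20)
  tr <- detect_sap(fake_track(ecc), dp)
  expect_equal(tr$second_flags, c(0L, 1L, 0L, 0L))  # partial 4th second
  expect_length(tr$second_flags, 4)                 # 35 frames -> 3.5 s
  # a positive second requires at least one positive frame
  expect_true(all(tr$second_flags[rowsum(tr$frame_flags,
    floor((0:34) / 10))[, 1] == 0] == 0))
})

test_that("summaries count duration, percentage and bouts", {
  dp <- detection_params(0.90, 12, 10)
  # 3000 frames (5 min), 311 positive frames in 9 runs
  lens <- c(40, 30, 50, 20, 35, 45, 25, 36, 30)
  stopifnot(sum(lens) == 311)
  ecc <- rep(0.5, 3000)
  pos <- 1
  for (L in lens) {
    ecc[pos:(pos + L - 1)] <- 0.95
    pos <- pos + L + 60
  }
  s <- summarize_sap(detect_sap(fake_track(ecc), dp))
  expect_equal(s$duration_s, 31.1)
  expect_equal(s$bouts, 9)
  expect_equal(s$freq_per_min, 9 / 5)
  expect_equal(s$sap_percent, 100 * 31.1 / 300)

  z <- summarize_sap(detect_sap(fake_track(rep(0.5, 100)), dp))
  expect_equal(unlist(z[c("duration_s", "sap_percent", "bouts",
                          "freq_per_min")]),
               c(duration_s = 0, sap_percent = 0, bouts = 0,
                 freq_per_min = 0))

  full <- summarize_sap(detect_sap(fake_track(rep(0.95, 100)), dp))
  expect_equal(full$bouts, 1)
  expect_equal(full$sap_percent, 100)
})
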