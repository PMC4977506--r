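# Independent oracles and small fixture builders used across the tests.

# Render a filled (optionally rotated) ellipse mask on an n x n pixel grid,
# centered, semi-axes in px. Pixel centers at integer coordinates.
ellipse_mask <- function(n, a, b, theta = 0, cx = (n - 1) / 2,
                         cy = (n - 1) / 2) {
  g <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  dx <- g$x - cx
  dy <- g$y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  matrix((u / a)^2 + (v / b)^2 <= 1, nrow = n)
}

# Brute-force moment ellipse: explicit loops over pixels, eigen() for the
# axes. Independent of fit_ellipse's closed-form path.
brute_moment_ecc <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  x <- px[, 2] - 1
  y <- px[, 1] - 1
  sxx <- 0; syy <- 0; sxy <- 0
  mx <- mean(x); my <- mean(y)
  for (i in seq_along(x)) {
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
  }
  n <- length(x)
  cov <- matrix(c(sxx / n + 1 / 12, sxy / n, sxy / n, syy / n + 1 / 12), 2)
  ev <- sort(eigen(cov, symmetric = TRUE)$values, decreasing = TRUE)
  sqrt(1 - ev[2] / ev[1])
}

# Brute-force bout filter: scan runs one by one.
brute_bout_filter <- function(flags, max_len) {
  out <- as.integer(flags)
  i <- 1L
  n <- length(out)
  while (i <= n) {
    if (out[i] == 1L) {
      j <- i
      while (j < n && out[j + 1L] == 1L) j <- j + 1L
      if (j - i + 1L <= max_len) out[i:j] <- 0L
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Brute-force 8-connected labeling by flood fill (stack-based).
brute_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextlab <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- nextlab
      r <- ((p - 1L) %% nrow(mask)) + 1L
      cc <- ((p - 1L) %/% nrow(mask)) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 >= 1L && r2 <= nrow(mask) && c2 >= 1L && c2 <= ncol(mask) &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          stack <- c(stack, (c2 - 1L) * nrow(mask) + r2)
        }
      }
    }
  }
  lab
}

# Write a list of [0,1] matrices as a multi-page TIFF, return the path.
write_pages <- function(pages, bits = 8L) {
  p <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, p, bits.per.sample = bits)
  p
}

# Scenarios whose analytic SAP truth straddles the (0.90, 12 cm/s)
# thresholds: one eccentricity staircase at rest, one speed staircase while
# elongated. Used by threshold-recovery tests.
recovery_scenarios <- function(seed = 1L, fps = 10) {
  seg <- 20L  # frames per level (2 s)
  ecc_levels <- c(0.86, 0.895, 0.905, 0.95)
  a <- 3.5
  b_levels <- a * sqrt(1 - ecc_levels^2)
  sA <- synth_scenario(a_cm = a, b_cm = rep(b_levels, each = seg),
                       n_frames = seg * length(ecc_levels), fps = fps,
                       seed = seed * 1000L + 1L)
  speed_levels <- c(0, 11, 13, 20)
  x <- numeric(0)
  pos <- 15
  dir <- 1
  for (sp in speed_levels) {
    step <- sp / fps
    for (i in seq_len(seg)) {
      x <- c(x, pos)
      if (pos + dir * step > 25 || pos + dir * step < 5) dir <- -dir
      pos <- pos + dir * step
    }
  }
  sB <- synth_scenario(a_cm = a, b_cm = a * sqrt(1 - 0.95^2),
                       n_frames = seg * length(speed_levels), fps = fps,
                       x_cm = x, y_cm = 15, seed = seed * 1000L + 2L)
  list(render_scenario(sA), render_scenario(sB))
}
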