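test_that("consensus is a strict majority, ties to 0", {
  expect_equal(consensus(matrix(c(1, 1, 0, 1, 0), ncol = 1)), 1L)
  expect_equal(consensus(matrix(c(0, 0, 1, 0, 0), ncol = 1)), 0L)
  expect_equal(consensus(matrix(c(1, 1, 0, 0), ncol = 1)), 0L)  # 4-rater tie
  # idempotent under duplicating the panel
  set.seed(2)
  panel <- matrix(rbinom(5 * 40, 1, 0.3), nrow = 5)
  expect_equal(consensus(rbind(panel, panel)), consensus(panel))
  expect_error(consensus(matrix(c(0, 2), ncol = 1)), "0/1")
})

test_that("confusion counts partition the compared seconds", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 1))
  same <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(c(same$tp, same$tn, same$fp, same$fn), c(2, 1, 0, 0))
  anti <- confusion(c(1, 0), c(0, 1))
  expect_equal(c(anti$tp, anti$tn), c(0, 0))
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "unequal score lengths")
})

# confusion tables rebuilt from each study's printed class totals and rates
of_counts <- confusion_counts(tp = 286, fp = 234, fn = 51, tn = 2429)
epm_counts <- confusion_counts(tp = 1771, fp = 491, fn = 288, tn = 2850)

test_that("accuracy, sensitivity and specificity from reconstructed counts", {
  of <- basic_metrics(of_counts)
  expect_equal(round(of$accuracy, 3), 0.905)
  expect_equal(round(of$sensitivity, 3), 0.849)
  expect_equal(round(of$specificity, 3), 0.912)
  expect_equal(round(basic_metrics(epm_counts)$accuracy, 3), 0.856)

  perfect <- basic_metrics(confusion_counts(10, 0, 0, 90))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1))
})

test_that("accuracy is the prevalence-weighted mean of sens and spec", {
  set.seed(9)
  for (i in 1:20) {
    cc <- do.call(confusion_counts, as.list(rpois(4, 30) + 1))
    bm <- basic_metrics(cc)
    expect_equal(bm$accuracy,
                 (bm$sensitivity * cc$P + bm$specificity * cc$N) /
                   (cc$P + cc$N))
  }
})

test_that("Wald interval has the closed-form half width and 1/sqrt(n) scaling", {
  ci <- wald_ci(50, 100, 0.95)
  expect_equal(ci$upper - ci$estimate, qnorm(0.975) * 0.05, tolerance = 1e-9)
  expect_equal(wald_ci(100, 100)$upper, 1)      # clamped at p = 1
  expect_equal(wald_ci(0, 50)$lower, 0)
  expect_equal(round(wald_ci(2715, 3000, 0.99)$upper, 3), 0.919)
  w <- function(n) { c <- wald_ci(round(0.3 * n), n); c$upper - c$lower }
  expect_equal(w(400) / w(100), 1 / 2, tolerance = 0.02)
})

test_that("F-score and MCC reproduce the reconstructed-count values", {
  expect_equal(round(f_score(of_counts), 3), 0.667)
  expect_equal(f_score(confusion_counts(10, 0, 0, 90)), 1)
  expect_equal(f_score(confusion_counts(0, 5, 5, 90)), 0)
  expect_equal(round(mcc(of_counts), 3), 0.635)
  expect_equal(mcc(confusion_counts(10, 0, 0, 90)), 1)
  # independence: tp*tn = fp*fn
  expect_equal(mcc(confusion_counts(6, 4, 3, 2)), 0)
  # degenerate denominator convention
  expect_equal(mcc(confusion_counts(0, 0, 5, 5)), 0)
})

test_that("swapping the prediction labels negates the MCC", {
  set.seed(13)
  for (i in 1:20) {
    cc <- do.call(confusion_counts, as.list(rpois(4, 20) + 1))
    swapped <- confusion_counts(cc$fp, cc$tp, cc$tn, cc$fn)
    expect_equal(mcc(swapped), -mcc(cc), tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC matches hand sums and rejects bad input", {
  expect_equal(auc_trapezoid(data.frame(fpr = c(0, 1), tpr = c(0, 1))), 0.5)
  expect_equal(auc_trapezoid(data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))), 1)
  # hand sum: 0.2*0.3 + 0.3*0.75 + 0.5*0.95
  expect_equal(
    auc_trapezoid(data.frame(fpr = c(0, 0.2, 0.5, 1),
                             tpr = c(0, 0.6, 0.9, 1))), 0.76)
  expect_error(auc_trapezoid(data.frame(fpr = c(0, 0.5, 0.2, 1),
                                        tpr = c(0, 0.5, 0.6, 1))), "sorted")
  expect_error(auc_trapezoid(data.frame(fpr = c(0.1, 1), tpr = c(0, 1))),
               "anchors")
})

make_eval_track <- function(n, seed, block = 10L) {
  # piecewise-constant traces: postures persist, so runs survive the
  # half-second bout filter
  set.seed(seed)
  k <- ceiling(n / block)
  data.frame(eccentricity = rep(runif(k, 0.7, 1), each = block)[1:n],
             speed_cms = rep(runif(k, 0, 25), each = block)[1:n],
             valid = TRUE)
}

test_that("the grid point generating the truth is a perfect operating point", {
  tr <- make_eval_track(600, 21)
  truth <- detect_sap(tr, detection_params(0.90, 12, 10))$second_flags
  rr <- roc_over_grid(tr, truth, ecc_grid = c(0.85, 0.90, 0.95),
                      speed_grid = c(8, 12, 16), fps = 10)
  at <- rr$surface[rr$surface$ecc_threshold == 0.90 &
                     rr$surface$speed_threshold == 12, ]
  expect_equal(at$tpr, 1)
  expect_equal(at$fpr, 0)
  expect_equal(at$mcc, 1)
  opt <- optimize_thresholds(rr)
  expect_equal(opt$ecc_threshold, 0.90)
  expect_equal(opt$speed_threshold, 12)
})

test_that("a degenerate grid yields anchors plus one point", {
  tr <- make_eval_track(100, 22)
  truth <- detect_sap(tr, detection_params(0.9, 12, 10))$second_flags
  rr <- roc_over_grid(tr, truth, 0.9, 12, fps = 10)
  expect_equal(nrow(rr$roc), 3)
  expect_error(roc_over_grid(tr, truth, numeric(0), 12, fps = 10),
               "empty threshold grid")
})

test_that("truth independent of the scores gives chance-level AUC", {
  tr <- make_eval_track(30000, 23)
  truth <- rbinom(3000, 1, 0.3)
  rr <- roc_over_grid(tr, truth, ecc_grid = seq(0.72, 0.98, 0.02),
                      speed_grid = 24, fps = 10)
  expect_equal(rr$auc, 0.5, tolerance = 0.05)
})

test_that("threshold ties resolve toward specificity", {
  surface <- data.frame(ecc_threshold = c(0.88, 0.90, 0.90),
                        speed_threshold = c(12, 10, 12),
                        mcc = c(0.9, 0.9, 0.9))
  opt <- optimize_thresholds(surface)
  expect_equal(opt$ecc_threshold, 0.90)
  expect_equal(opt$speed_threshold, 12)
  expect_error(optimize_thresholds(data.frame(ecc_threshold = 1,
                                              speed_threshold = 1,
                                              mcc = NA)), "undefined")
})

test_that("ICC(A,k) is exact for perfect agreement and tracks disagreement", {
  set.seed(31)
  base <- rbinom(60, 1, 0.4)
  same <- matrix(rep(base, each = 5), nrow = 5)
  expect_identical(icc_two_way_average(same)$icc, 1)

  noisy <- same
  noisy[5, ] <- rbinom(60, 1, 0.5)  # one rater scores independently
  expect_lt(icc_two_way_average(noisy)$icc, 1)

  expect_warning(icc_two_way_average(matrix(1, 3, 10)), "degenerate")
})

test_that("ICC mean squares match a two-way ANOVA fit", {
  set.seed(33)
  k <- 4; n <- 25
  y <- matrix(rnorm(k * n), k, n) + rep(rnorm(n), each = k) +
    rnorm(k)[rep(1:k, n)]
  ours <- icc_two_way_average(y)
  d <- data.frame(y = as.vector(y),
                  rater = factor(rep(1:k, n)),
                  subject = factor(rep(1:n, each = k)))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]]$`Mean Sq`
  expect_equal(ours$msr, ms[1], tolerance = 1e-10)
  expect_equal(ours$msc, ms[2], tolerance = 1e-10)
  expect_equal(ours$mse, ms[3], tolerance = 1e-10)
  expect_equal(ours$icc, (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / n),
               tolerance = 1e-10)
})

test_that("rater panels load in either orientation", {
  panel <- matrix(rbinom(5 * 8, 1, 0.4), nrow = 5)
  # rows = raters, no header
  p1 <- tempfile(fileext = ".csv")
  write.table(panel, p1, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(read_rater_panel(p1), panel)
  # columns = raters, headed rater1..rater5, with a leading seconds column
  p2 <- tempfile(fileext = ".csv")
  wide <- as.data.frame(t(panel))
  names(wide) <- paste0("rater", 1:5)
  write.csv(cbind(second = 0:7, wide), p2, row.names = FALSE)
  expect_equal(read_rater_panel(p2), panel)
})
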