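#' Majority-vote consensus of a rater panel
#'
#' Per second, the consensus is 1 iff strictly more than half of the raters
#' scored 1. With an even rater count an exact tie resolves to 0: calling
#' SAP requires a true majority.
#'
#' @param panel Integer/numeric matrix of 0/1 scores, one row per rater and
#'   one column per second (see [read_rater_panel()]).
#' @return Integer 0/1 vector, one entry per second.
#' @examples
#' consensus(rbind(c(1, 0, 1), c(1, 0, 0), c(0, 1, 1), c(1, 1, 0), c(1, 0, 1)))
#' @export
consensus <- function(panel) {
  panel <- validate_panel(panel)
  as.integer(colSums(panel) > nrow(panel) / 2)
}

validate_panel <- function(panel) {
  panel <- as.matrix(panel)
  if (anyNA(panel) || !all(panel %in% c(0, 1))) {
    stop("rater panel must contain only 0/1 scores with no missing values")
  }
  if (nrow(panel) < 1L || ncol(panel) < 1L) stop("empty rater panel")
  storage.mode(panel) <- "integer"
  panel
}

#' Read a rater score table
#'
#' Reads a delimited text file of per-second binary scores. Orientation is
#' auto-detected from the header: if the column names look like rater labels
#' (they start with "rater", case-insensitive), columns are raters and rows
#' seconds; otherwise each row is a rater. An optional leading
#' `second`/`time` column is dropped.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the first
#'   line).
#' @return An R x S integer matrix, rows = raters, columns = seconds.
#' @export
read_rater_panel <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = has_header, sep = sep)
  time_col <- grepl("^(second|time)", names(tab), ignore.case = TRUE)
  tab <- tab[, !time_col, drop = FALSE]
  m <- as.matrix(tab)
  if (has_header && all(grepl("^rater", colnames(tab), ignore.case = TRUE))) {
    m <- t(m)  # columns were raters
  }
  dimnames(m) <- NULL
  validate_panel(m)
}

#' Confusion counts of predicted vs. reference per-second scores
#'
#' @param pred,truth Equal-length 0/1 vectors (prediction and reference,
#'   e.g. detector seconds vs. human consensus).
#' @return A list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`
#'   and the class totals `P = tp + fn`, `N = fp + tn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("unequal score lengths")
  stopifnot(all(pred %in% c(0, 1)), all(truth %in% c(0, 1)))
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  confusion_counts(tp, fp, fn, tn)
}

#' Build confusion counts directly
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 P = tp + fn, N = fp + tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d (P=%d, N=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$P, x$N))
  invisible(x)
}

#' Accuracy, sensitivity and specificity
#'
#' @param c A `confusion_counts` object.
#' @return A list with `accuracy`, `sensitivity`, `specificity` as
#'   proportions in \[0, 1\]. Sensitivity is `NA` (with a warning) when
#'   there are no positives, specificity when there are no negatives.
#' @export
basic_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  sens <- if (c$P > 0) c$tp / c$P else {
    warning("no positive seconds: sensitivity undefined"); NA_real_
  }
  spec <- if (c$N > 0) c$tn / c$N else {
    warning("no negative seconds: specificity undefined"); NA_real_
  }
  list(accuracy = (c$tp + c$tn) / (c$P + c$N),
       sensitivity = sens, specificity = spec)
}

#' Wald (normal-approximation) binomial confidence interval
#'
#' \eqn{p \pm z \sqrt{p(1-p)/n}}, bounds clamped to \[0, 1\]. Adequate when
#' n > 30 and p is not close to 0 or 1, which holds for whole-study
#' second counts.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (> 0).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A list of class `binomial_ci`: `estimate`, `lower`, `upper`,
#'   `level`, `n`.
#' @examples
#' wald_ci(2715, 3000, level = 0.99)
#' @export
wald_ci <- function(successes, n, level = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n, level > 0, level < 1)
  p <- successes / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(p * (1 - p) / n)
  structure(list(estimate = p,
                 lower = max(0, p - hw),
                 upper = min(1, p + hw),
                 level = level, n = n),
            class = "binomial_ci")
}

#' F-score (harmonic mean of precision and recall)
#'
#' @param c A `confusion_counts` object with at least one predicted and one
#'   actual positive. If nothing was predicted positive the score is
#'   returned as 0 with a warning.
#' @return Value in \[0, 1\].
#' @export
f_score <- function(c) {
  stopifnot(inherits(c, "confusion_counts"), c$P > 0)
  if (c$tp + c$fp == 0) {
    warning("no predicted positives: F-score undefined, returning 0")
    return(0)
  }
  precision <- c$tp / (c$tp + c$fp)
  recall <- c$tp / c$P
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Matthews correlation coefficient
#'
#' A balanced association measure for a 2x2 confusion table, in \[-1, 1\];
#' preferred over the F-score when the classes are imbalanced, as SAP
#' seconds are rare relative to non-SAP seconds. Any zero factor in the
#' denominator makes the correlation undefined; by convention 0 (no
#' correlation) is returned.
#'
#' @param c A `confusion_counts` object.
#' @return Value in \[-1, 1\].
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)  # doubles: the products
  fn <- as.numeric(c$fn); tn <- as.numeric(c$tn)  # overflow integers
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Area under a curve by the simple trapezoidal method
#'
#' @param points A data frame (or matrix) with columns `fpr` and `tpr`,
#'   sorted by non-decreasing `fpr`, containing the anchors (0, 0) and
#'   (1, 1).
#' @return The trapezoidal sum \eqn{\sum (x_{i+1}-x_i)(y_i+y_{i+1})/2}.
#' @examples
#' auc_trapezoid(data.frame(fpr = c(0, 1), tpr = c(0, 1)))       # 0.5
#' auc_trapezoid(data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))) # 1
#' @export
auc_trapezoid <- function(points) {
  points <- as.data.frame(points)
  x <- points$fpr
  y <- points$tpr
  stopifnot(length(x) >= 2L, length(x) == length(y))
  if (is.unsorted(x)) stop("ROC points must be sorted by non-decreasing fpr")
  if (!(x[1L] == 0 && y[1L] == 0 && x[length(x)] == 1 && y[length(y)] == 1)) {
    stop("ROC points must include the (0,0) and (1,1) anchors")
  }
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

#' ROC points and MCC surface over a threshold grid
#'
#' For every (eccentricity, speed) threshold pair in the grid, re-runs the
#' SAP gating (including the half-second bout filter and per-second
#' aggregation) on the supplied frame tracks, compares the pooled per-second
#' flags with the reference scores, and records the operating point
#' (fpr = 1 - specificity, tpr = sensitivity) and the MCC. A 1-D ROC curve
#' is obtained by passing a single-element grid for the other threshold.
#'
#' @param tracks A `sap_track` or a list of them (one per video).
#' @param truths A 0/1 per-second vector or a list of them, aligned with
#'   `tracks`. Extra trailing entries on either side per video are
#'   truncated to the common length.
#' @param ecc_grid,speed_grid Numeric vectors of candidate thresholds.
#' @param fps Frame rate; defaults to the `fps` attribute of the first
#'   track.
#' @return A list of class `roc_result`: `roc` (data frame `fpr`, `tpr`,
#'   `ecc_threshold`, `speed_threshold`, sorted by fpr then tpr, with
#'   anchors), `auc`, and `surface` (long data frame `ecc_threshold`,
#'   `speed_threshold`, `tpr`, `fpr`, `mcc`).
#' @seealso [optimize_thresholds()]
#' @export
roc_over_grid <- function(tracks, truths, ecc_grid, speed_grid, fps = NULL) {
  if (inherits(tracks, "data.frame")) tracks <- list(tracks)
  if (!is.list(truths)) truths <- list(truths)
  stopifnot(length(tracks) == length(truths))
  if (length(ecc_grid) == 0L || length(speed_grid) == 0L) {
    stop("empty threshold grid")
  }
  if (is.null(fps)) fps <- attr(tracks[[1L]], "fps")
  grid <- expand.grid(ecc_threshold = ecc_grid,
                      speed_threshold = speed_grid)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    pred <- integer(0)
    ref <- integer(0)
    for (v in seq_along(tracks)) {
      trace <- detect_sap(tracks[[v]],
                          detection_params(grid$ecc_threshold[k],
                                           grid$speed_threshold[k], fps))
      s <- min(length(trace$second_flags), length(truths[[v]]))
      pred <- c(pred, trace$second_flags[seq_len(s)])
      ref <- c(ref, truths[[v]][seq_len(s)])
    }
    cc <- confusion(pred, ref)
    bm <- basic_metrics(cc)
    c(tpr = bm$sensitivity, fpr = 1 - bm$specificity, mcc = mcc(cc))
  })
  res <- do.call(rbind, res)
  surface <- cbind(grid, as.data.frame(res))
  pts <- data.frame(fpr = c(0, res[, "fpr"], 1),
                    tpr = c(0, res[, "tpr"], 1),
                    ecc_threshold = c(NA, grid$ecc_threshold, NA),
                    speed_threshold = c(NA, grid$speed_threshold, NA))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  structure(list(roc = pts, auc = auc_trapezoid(pts), surface = surface),
            class = "roc_result")
}

#' Pick the threshold pair maximizing the MCC
#'
#' The operating point with the maximum MCC over the grid is the optimal
#' threshold pair; exact ties are broken toward the higher eccentricity
#' threshold, then the higher speed threshold (preferring specificity).
#'
#' @param surface The `surface` data frame from [roc_over_grid()] (or a
#'   `roc_result`), with columns `ecc_threshold`, `speed_threshold`, `mcc`.
#' @return A list with `ecc_threshold`, `speed_threshold` and `mcc`.
#' @export
optimize_thresholds <- function(surface) {
  if (inherits(surface, "roc_result")) surface <- surface$surface
  stopifnot(nrow(surface) > 0)
  m <- surface$mcc
  if (all(is.na(m))) stop("MCC undefined over the whole grid")
  best <- which(m == max(m, na.rm = TRUE))
  o <- order(surface$ecc_threshold[best], surface$speed_threshold[best],
             decreasing = TRUE)
  b <- best[o[1L]]
  list(ecc_threshold = surface$ecc_threshold[b],
       speed_threshold = surface$speed_threshold[b],
       mcc = surface$mcc[b])
}

#' Two-way agreement average-measure intraclass correlation, ICC(A,k)
#'
#' Inter-rater reliability of the *average* of k raters' scores across
#' subjects (here: seconds), under the two-way model with absolute
#' agreement (McGraw & Wong ICC(A,k)). With the two-way ANOVA mean squares
#' -- `MSR` between subjects, `MSC` between raters, `MSE` residual, for n
#' subjects and k raters:
#' \deqn{ICC(A,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}}
#' where
#' `MSR = k * sum((subject_mean - grand)^2) / (n - 1)`,
#' `MSC = n * sum((rater_mean - grand)^2) / (k - 1)`,
#' `MSE = sum((y - subject_mean - rater_mean + grand)^2) / ((n-1)(k-1))`.
#' The binary per-second scores are fed to this continuous-model statistic
#' as-is, the field's standard practice for rater panels.
#'
#' @param panel R x S matrix of scores, rows = raters (k = R >= 2),
#'   columns = subjects/seconds (n = S >= 2).
#' @return A list of class `icc_result`: `icc` (<= 1; 1 for perfect
#'   agreement, `NA` with a warning for an all-constant panel),
#'   `n_subjects`, `n_raters`, and the mean squares `msr`, `msc`, `mse`.
#' @export
icc_two_way_average <- function(panel) {
  panel <- as.matrix(panel)
  k <- nrow(panel)
  n <- ncol(panel)
  stopifnot(k >= 2L, n >= 2L)
  grand <- mean(panel)
  sub_means <- colMeans(panel)
  rat_means <- rowMeans(panel)
  msr <- k * sum((sub_means - grand)^2) / (n - 1)
  msc <- n * sum((rat_means - grand)^2) / (k - 1)
  resid <- sweep(sweep(panel, 2L, sub_means), 1L, rat_means) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  num <- msr - mse
  den <- msr + (msc - mse) / n
  icc <- if (den == 0) {
    if (num == 0) {
      warning("all-constant panel: ICC degenerate")
      NA_real_
    } else 1
  } else if (num == 0 && msr == 0 && msc == 0 && mse == 0) {
    warning("all-constant panel: ICC degenerate")
    NA_real_
  } else num / den
  structure(list(icc = icc, n_subjects = n, n_raters = k,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(A,%d) = %.3f over %d subjects\n",
              x$n_raters, x$icc, x$n_subjects))
  invisible(x)
}
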