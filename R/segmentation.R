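#' Binarize a frame by background subtraction
#'
#' Subtracts the empty-arena background from a frame, clamps negative
#' residuals to zero (a bright animal on a dark arena only adds intensity;
#' negative residuals are noise), and thresholds.
#'
#' @param frame,background Numeric matrices of identical shape, intensities
#'   in \[0, 1\].
#' @param threshold Binarization threshold in (0, 1), applied to the clamped
#'   difference.
#' @return A logical matrix (`TRUE` = foreground) of the same shape.
#' @examples
#' bg <- matrix(0.1, 50, 50)
#' fr <- bg; fr[20:30, 20:40] <- 0.9
#' sum(binarize_frame(fr, bg, 0.5))
#' @export
binarize_frame <- function(frame, background, threshold) {
  if (!identical(dim(frame), dim(background))) {
    stop("incompatible frames: frame and background dimensions differ")
  }
  stopifnot(threshold > 0, threshold < 1)
  pmax(frame - background, 0) > threshold
}

# Disk structuring element of the given pixel radius (odd-sized brush).
disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}

#' Remove the tail by morphological opening
#'
#' Erodes and then dilates the mask with a disk structuring element
#' (morphological opening). Structures thinner than twice the radius -- the
#' tail -- are eliminated, while the body is restored to approximately its
#' original girth and length. The tail must be removed before ellipse
#' fitting: its length and changing position otherwise distort the
#' eccentricity.
#'
#' @param mask Logical matrix (foreground = `TRUE`).
#' @param morph_radius_px Non-negative integer disk radius in pixels;
#'   0 is the identity. The package-level default is expressed physically
#'   as 0.25 cm and converted via the video calibration (see
#'   [track_frames()]), making it resolution-invariant.
#' @return Logical matrix; a subset of the dilation of `mask`, empty if the
#'   mask is everywhere thinner than the structuring element.
#' @examples
#' m <- matrix(FALSE, 60, 60)
#' m[20:34, 10:50] <- TRUE        # body
#' m[26:28, 51:60] <- TRUE        # tail stub
#' sum(remove_tail(m, 3)) / sum(m[20:34, 10:50])
#' @export
remove_tail <- function(mask, morph_radius_px) {
  stopifnot(is.logical(mask), is.matrix(mask), morph_radius_px >= 0)
  if (morph_radius_px == 0) return(mask)
  r <- as.integer(morph_radius_px)
  # pad with background so pixels beyond the frame do not count as
  # foreground during erosion (EBImage replicates the border)
  padded <- matrix(0, nrow(mask) + 2L * r, ncol(mask) + 2L * r)
  padded[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))] <- mask * 1
  opened <- EBImage::opening(padded, disc_brush(r))
  matrix(as.numeric(opened) > 0.5,
         nrow = nrow(padded))[r + seq_len(nrow(mask)),
                              r + seq_len(ncol(mask)), drop = FALSE]
}

# 8-connected component labeling. Returns an integer matrix, 0 = background.
# Adjacency edges (E, S, SE, SW neighbors) are built vectorized and the
# components come from igraph; EBImage's labeler is 4-connected.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  nc <- ncol(mask)
  node <- match(idx, idx)  # 1..k in index order
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + sh[1L]
    c2 <- col + sh[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    if (any(hit)) {
      edges[[length(edges) + 1L]] <-
        cbind(node[ok][hit], match(nb[hit], idx))
    }
  }
  if (length(edges) > 0L) {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
    lab[idx] <- igraph::components(g)$membership
  } else {
    lab[idx] <- seq_along(idx)
  }
  lab
}

#' Keep only the largest connected component
#'
#' Selects the 8-connected foreground component with the most pixels;
#' everything else (stray reflections, leftover tail fragments) is dropped.
#' An exact size tie is broken deterministically: the component whose
#' topmost-then-leftmost pixel comes first in (row, column) order wins.
#'
#' An all-`FALSE` input is not an error -- the animal may be absent from a
#' frame -- and yields an all-`FALSE` mask whose `"empty"` attribute is
#' `TRUE`, which downstream code converts to an invalid frame.
#'
#' @param mask Logical matrix.
#' @return Logical matrix holding the winning component only, with a logical
#'   attribute `"empty"`.
#' @export
largest_component <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- label_components(mask)
  if (all(lab == 0L)) {
    return(structure(matrix(FALSE, nrow(mask), ncol(mask)), empty = TRUE))
  }
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: lexicographically smallest (row, col) among each component's
    # minimum pixel
    nr <- nrow(mask)
    keys <- vapply(best, function(b) {
      px <- which(lab == b)
      r <- ((px - 1L) %% nr) + 1L
      cc <- ((px - 1L) %/% nr) + 1L
      o <- order(r, cc)[1L]
      r[o] * (ncol(mask) + 1) + cc[o]
    }, numeric(1L))
    best <- best[which.min(keys)]
  }
  structure(lab == best, empty = FALSE)
}
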