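#' Axis-aligned boxes, anchors and box-delta coding
#'
#' Boxes live in continuous image coordinates with the origin at the top-left
#' corner, x rightward and y downward, and are half-open: a box covers
#' `[x, x + w) x [y, y + h)`.  Pixel `(r, c)` of a raster has its center at
#' `(c - 0.5, r - 0.5)`.  A box is a data frame (or one row of one) with
#' columns `x`, `y`, `w`, `h`; anchors additionally carry `level` (pyramid
#' stride) and `ratio`.
#'
#' @param x,y Top-left corner in pixels.
#' @param w,h Width and height in pixels (strictly positive).
#' @return A one-row data frame of class box.
#' @examples
#' b <- box(0, 0, 10, 5)
#' iou(b, box(5, 0, 10, 5))
#' @export
box <- function(x, y, w, h) {
  if (any(w <= 0) || any(h <= 0)) stop("box dimensions must be positive")
  data.frame(x = x, y = y, w = w, h = h)
}

#' Intersection over union of boxes or masks
#'
#' For two box sets this is computed analytically and vectorised: the result
#' is an `nrow(a) x nrow(b)` matrix.  For two binary masks of equal shape it
#' is computed by pixel counting.  An empty union (both masks empty) is an
#' error, not zero: the ratio is undefined.
#'
#' @param a,b Box data frames, or logical/0-1 matrices of identical shape.
#' @return IoU matrix (boxes) or a single fraction in `[0, 1]` (masks).
#' @export
iou <- function(a, b) {
  if (is.matrix(a) && is.matrix(b)) {
    if (!all(dim(a) == dim(b))) stop("mask shapes differ")
    a <- a > 0; b <- b > 0
    un <- sum(a | b)
    if (un == 0) stop("IoU undefined: both masks are empty")
    return(sum(a & b) / un)
  }
  ix1 <- outer(a$x, b$x, pmax)
  iy1 <- outer(a$y, b$y, pmax)
  ix2 <- outer(a$x + a$w, b$x + b$w, pmin)
  iy2 <- outer(a$y + a$h, b$y + b$h, pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  un <- outer(a$w * a$h, b$w * b$h, `+`) - inter
  out <- inter / un
  if (length(out) == 1) out[1, 1] else out
}

#' Encode ground-truth boxes against anchors
#'
#' The parameterization is `t_x = (x* - x_a)/w_a`, `t_y = (y* - y_a)/h_a`,
#' `t_w = log(w*/w_a)`, `t_h = log(h*/h_a)` with natural logarithms; `decode`
#' is its exact algebraic inverse.  Both are vectorised row-wise.
#'
#' @param gt,anchor Box data frames with matching row counts (or one row
#'   recycled).
#' @return Data frame with columns `tx`, `ty`, `tw`, `th`.
#' @export
encode_boxes <- function(gt, anchor) {
  if (any(gt$w <= 0) || any(gt$h <= 0)) stop("ground-truth box dimensions must be positive")
  data.frame(
    tx = (gt$x - anchor$x) / anchor$w,
    ty = (gt$y - anchor$y) / anchor$h,
    tw = log(gt$w / anchor$w),
    th = log(gt$h / anchor$h)
  )
}

#' @param delta Data frame with columns `tx`, `ty`, `tw`, `th`.
#' @param max_dim Optional clip: decoded sides larger than this are clamped
#'   (with a warning) to guard against exploded `exp(t_w)` early in training.
#' @rdname encode_boxes
#' @export
decode_boxes <- function(delta, anchor, max_dim = NULL) {
  w <- anchor$w * exp(delta$tw)
  h <- anchor$h * exp(delta$th)
  if (!is.null(max_dim) && any(c(w, h) > max_dim)) {
    warning("decoded box clipped to max_dim")
    w <- pmin(w, max_dim); h <- pmin(h, max_dim)
  }
  data.frame(x = anchor$x + delta$tx * anchor$w,
             y = anchor$y + delta$ty * anchor$h, w = w, h = h)
}

#' Tile anchors over a square image
#'
#' One anchor per (grid cell, scale, ratio) at every pyramid level; the grid
#' stride is the level itself and anchors are centered on cell centers.  The
#' row order within a level is grid-row fastest, then grid-column, then the
#' (scale, ratio) variant -- the same order in which the proposal head emits
#' its per-anchor channels.  `ratio` is height/width; anchors may extend past
#' the image border and are flagged `inside`.
#'
#' @param image_size Side of the (square) image in pixels.
#' @param levels Integer strides, e.g. `c(4, 8, 16)`.
#' @param scales_per_level List (parallel to `levels`) of anchor side lengths
#'   in pixels; defaults to `4 * stride * 2^(0:2/3)`.
#' @param ratios Height/width aspect ratios.
#' @return Anchor data frame: `x,y,w,h,level,ratio,inside`.
#' @export
make_anchors <- function(image_size, levels = c(4L, 8L, 16L),
                         scales_per_level = NULL,
                         ratios = c(1 / 3, 0.5, 1, 2, 3)) {
  if (length(levels) == 0 || length(ratios) == 0) stop("levels and ratios must be non-empty")
  if (is.null(scales_per_level))
    scales_per_level <- lapply(levels, function(s) 4 * s * 2^((0:2) / 3))
  out <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    s <- levels[li]
    n <- image_size %/% s
    variants <- expand.grid(scale = scales_per_level[[li]], ratio = ratios)
    g <- expand.grid(i = seq_len(n), j = seq_len(n), v = seq_len(nrow(variants)))
    sc <- variants$scale[g$v]; rt <- variants$ratio[g$v]
    wa <- sc / sqrt(rt); ha <- sc * sqrt(rt)
    cx <- (g$j - 0.5) * s; cy <- (g$i - 0.5) * s
    out[[li]] <- data.frame(x = cx - wa / 2, y = cy - ha / 2, w = wa, h = ha,
                            level = s, ratio = rt)
  }
  a <- do.call(rbind, out)
  a$inside <- a$x >= 0 & a$y >= 0 & a$x + a$w <= image_size & a$y + a$h <= image_size
  a
}

#' Assign anchors to ground-truth boxes
#'
#' An anchor is positive when its IoU with some ground-truth box reaches
#' `pos_thr`, or when it is the best anchor for a ground truth (so every
#' object with any overlap above `neg_thr` trains at least one anchor);
#' negative when its best IoU is below `neg_thr`; ignored otherwise.
#' Positives carry the index of their best ground truth and the encoded
#' regression target.
#'
#' @param anchors,gt_boxes Box data frames.
#' @param pos_thr,neg_thr Matching thresholds, `pos_thr > neg_thr`.
#' @return List: `label` (factor positive/negative/ignore), `gt_index`
#'   (NA for non-positives), `delta` (targets, NA rows for non-positives).
#' @export
match_anchors <- function(anchors, gt_boxes, pos_thr = 0.7, neg_thr = 0.3) {
  if (pos_thr <= neg_thr) stop("pos_thr must exceed neg_thr")
  n <- nrow(anchors)
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0) {
    return(list(label = factor(rep("negative", n), levels = c("positive", "negative", "ignore")),
                gt_index = rep(NA_integer_, n),
                delta = data.frame(tx = rep(NA_real_, n), ty = NA_real_, tw = NA_real_, th = NA_real_)))
  }
  m <- iou(anchors, gt_boxes)
  m <- matrix(m, nrow = n)
  best <- max.col(m, ties.method = "first")
  best_iou <- m[cbind(seq_len(n), best)]
  lab <- rep("ignore", n)
  lab[best_iou < neg_thr] <- "negative"
  lab[best_iou >= pos_thr] <- "positive"
  # force the argmax anchor of each gt positive (ties: first anchor)
  for (g in seq_len(ncol(m))) {
    if (max(m[, g]) > 0) {
      a <- which.max(m[, g])
      lab[a] <- "positive"
      best[a] <- g
    }
  }
  gi <- ifelse(lab == "positive", best, NA_integer_)
  delta <- data.frame(tx = rep(NA_real_, n), ty = NA_real_, tw = NA_real_, th = NA_real_)
  pos <- which(lab == "positive")
  if (length(pos))
    delta[pos, ] <- encode_boxes(gt_boxes[gi[pos], , drop = FALSE],
                                 anchors[pos, , drop = FALSE])
  list(label = factor(lab, levels = c("positive", "negative", "ignore")),
       gt_index = as.integer(gi), delta = delta)
}

#' Greedy non-maximum suppression
#'
#' Keeps boxes in decreasing score order, dropping any box whose IoU with an
#' already-kept box exceeds `thr`.
#'
#' @param boxes Box data frame.
#' @param scores Numeric vector parallel to `boxes`.
#' @param thr Overlap threshold in `[0, 1]`; `thr = 1` keeps everything.
#' @return Integer indices of kept rows, in decreasing score order.
#' @export
nms <- function(boxes, scores, thr) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord)) {
      ov <- iou(boxes[i, , drop = FALSE], boxes[ord, , drop = FALSE])
      ord <- ord[ov <= thr | (thr >= 1)]
    }
  }
  keep
}

# Tight bounding box of a binary mask, in continuous coordinates.
mask_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  box(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
      max(idx[, 2]) - min(idx[, 2]) + 1, max(idx[, 1]) - min(idx[, 1]) + 1)
}

# Bounding box of a polygon's vertices.
poly_bbox <- function(vertices, pad = 0) {
  x0 <- min(vertices[, 1]) - pad; y0 <- min(vertices[, 2]) - pad
  box(x0, y0, max(vertices[, 1]) + pad - x0, max(vertices[, 2]) + pad - y0)
}
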