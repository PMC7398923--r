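test_that("box IoU matches hand-computed and degenerate cases", {
  b <- box(0, 0, 2, 2)
  expect_equal(iou(b, b), 1.0)
  expect_equal(iou(b, box(10, 10, 2, 2)), 0.0)
  expect_equal(iou(b, box(1, 1, 2, 2)), 1 / 7)
})

test_that("box IoU agrees with pixel-counting on rasterized boxes", {
  set.seed(3)
  for (i in 1:20) {
    a <- random_box(64); b <- random_box(64)
    # integer-aligned boxes rasterize exactly
    a[] <- lapply(a, round); b[] <- lapply(b, round)
    a$w <- max(a$w, 1); a$h <- max(a$h, 1)
    b$w <- max(b$w, 1); b$h <- max(b$h, 1)
    ma <- matrix(FALSE, 64, 64); mb <- matrix(FALSE, 64, 64)
    ma[a$y + seq_len(a$h), a$x + seq_len(a$w)] <- TRUE
    mb[b$y + seq_len(b$h), b$x + seq_len(b$w)] <- TRUE
    expect_equal(iou(a, b), iou(ma, mb), tolerance = 1e-12)
  }
})

test_that("IoU of two empty masks is an error, not zero", {
  expect_error(iou(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), "undefined")
})

test_that("box-delta encoding matches the printed parameterization", {
  expect_equal(unlist(encode_boxes(box(0, 0, 10, 10), box(0, 0, 10, 10))),
               c(tx = 0, ty = 0, tw = 0, th = 0))
  d <- encode_boxes(box(5, 0, 20, 10), box(0, 0, 10, 10))
  expect_equal(d$tx, 0.5)
  expect_equal(d$ty, 0)
  expect_equal(d$tw, log(2))
  expect_equal(d$th, 0)
})

test_that("encode/decode are exact inverses over random pairs", {
  set.seed(5)
  gt <- do.call(rbind, lapply(1:100, function(i) random_box()))
  an <- do.call(rbind, lapply(1:100, function(i) random_box()))
  back <- decode_boxes(encode_boxes(gt, an), an)
  expect_lt(max(abs(as.matrix(back) - as.matrix(gt))), 1e-9)
})

test_that("anchor grids have one anchor per cell, scale and ratio", {
  a <- make_anchors(64, levels = 8L, scales_per_level = list(32), ratios = 1)
  expect_equal(nrow(a), 64)
  expect_true(all(a$w == 32 & a$h == 32))
  a3 <- make_anchors(64, levels = 8L, scales_per_level = list(32),
                     ratios = c(0.5, 1, 2))
  expect_equal(nrow(a3), 3 * 64)
  # centers at cell centers
  expect_equal(sort(unique(a$x + a$w / 2)), (1:8 - 0.5) * 8)
})

test_that("default anchors cover every synthetic ground-truth box at IoU 0.5", {
  anchors <- make_anchors(128)
  set.seed(17)
  for (i in 1:100) {
    im <- generate_insect(insect_spec(
      seed = i, n_wings = sample(1:2, 1), n_legs = sample(3:6, 1),
      leg_width_px = runif(1, 1, 3), body_axis_angle = runif(1, 0, 360)))
    gt <- image_ground_truth(im)
    best <- apply(iou(anchors[, c("x", "y", "w", "h")], gt$gt_boxes), 2, max)
    expect_true(all(best >= 0.5))
  }
})

test_that("anchor matching equals a brute-force double loop", {
  set.seed(9)
  for (rep in 1:10) {
    anchors <- do.call(rbind, lapply(1:20, function(i) random_box()))
    gts <- do.call(rbind, lapply(1:3, function(i) random_box()))
    got <- match_anchors(anchors, gts, pos_thr = 0.7, neg_thr = 0.3)
    # brute force
    m <- matrix(0, 20, 3)
    for (i in 1:20) for (g in 1:3) m[i, g] <- iou(anchors[i, ], gts[g, ])
    lab <- rep("ignore", 20)
    best <- apply(m, 1, which.max)
    bi <- m[cbind(1:20, best)]
    lab[bi < 0.3] <- "negative"
    lab[bi >= 0.7] <- "positive"
    for (g in 1:3) if (max(m[, g]) > 0) {
      lab[which.max(m[, g])] <- "positive"
      best[which.max(m[, g])] <- g
    }
    expect_identical(as.character(got$label), lab)
    pos <- which(lab == "positive")
    expect_equal(got$gt_index[pos], best[pos])
    for (k in pos) {
      expect_equal(unlist(got$delta[k, ]),
                   unlist(encode_boxes(gts[best[k], ], anchors[k, ])),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("matching labels are exclusive and empty gt gives all negatives", {
  anchors <- do.call(rbind, lapply(1:10, function(i) random_box()))
  m <- match_anchors(anchors, NULL)
  expect_true(all(m$label == "negative"))
  gt <- anchors[3, ]
  m2 <- match_anchors(anchors, gt)
  expect_equal(as.character(m2$label[3]), "positive")
  expect_equal(unname(unlist(m2$delta[3, ])), c(0, 0, 0, 0))
})

test_that("greedy NMS limits match the brute-force suppression", {
  set.seed(13)
  boxes <- do.call(rbind, lapply(1:20, function(i) random_box(64)))
  scores <- runif(20)
  expect_setequal(nms(boxes, scores, 1.0), seq_len(20))
  k0 <- nms(boxes, scores, 0.0)
  ov <- iou(boxes[k0, ], boxes[k0, ])
  diag(ov) <- 0
  expect_true(all(ov == 0))
  # brute-force greedy oracle
  oracle <- function(bx, sc, thr) {
    ord <- order(sc, decreasing = TRUE); keep <- integer(0)
    for (i in ord) {
      ok <- TRUE
      for (k in keep) if (iou(bx[i, ], bx[k, ]) > thr) ok <- FALSE
      if (ok) keep <- c(keep, i)
    }
    keep
  }
  for (thr in c(0.3, 0.5, 0.7))
    expect_identical(nms(boxes, scores, thr), oracle(boxes, scores, thr))
})
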