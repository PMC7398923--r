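#' Model configuration
#'
#' The network is a residual backbone with a feature pyramid, a region
#' proposal stage shared across pyramid levels, and three parallel heads
#' (classify, tighten, mask) over RoI-aligned patches.  The backbone depth
#' is configurable: `backbone_depth` residual stages follow a stride-4 stem,
#' giving pyramid strides `4 * 2^(0:backbone_depth)`.  The default is a tiny
#' two-stage net sized for 128 px images and CPU training; deeper settings
#' scale toward the ResNet-class configuration the method was designed
#' around, without changing any other code path.
#'
#' @param image_size Input side in pixels; must be a multiple of the
#'   largest pyramid stride.
#' @param backbone_depth Number of residual stages after the stem (>= 1).
#' @param base_channels Stem width; stage `i` has `2 * base_channels + 8 i`
#'   channels.
#' @param fpn_channels Uniform channel count of all pyramid levels.
#' @param roi_output_size RoIAlign output side for the box/class head (>= 7).
#' @param mask_resolution Side of the predicted square mask (default 28).
#'   The mask head works at this resolution on RoI-aligned pyramid features
#'   concatenated with the RoI-aligned raw image, so thin structures (1-2 px
#'   legs) stay resolvable below the coarsest feature stride.
#' @param proposals_per_image Proposal cap after non-maximum suppression.
#' @param anchor_ratios Height/width aspect ratios of the anchors.
#' @param seed Seed for He-uniform weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(image_size = 128, backbone_depth = 2,
                         base_channels = 8, fpn_channels = 16,
                         roi_output_size = 7, mask_resolution = 28,
                         proposals_per_image = 192,
                         anchor_ratios = c(1 / 3, 0.5, 1, 2, 3),
                         seed = 1L) {
  if (roi_output_size < 7) stop("roi_output_size must be >= 7")
  levels <- as.integer(4 * 2^(0:backbone_depth))
  if (image_size %% max(levels) != 0)
    stop("image_size must be a multiple of the largest pyramid stride (",
         max(levels), ")")
  structure(list(
    image_size = image_size, backbone_depth = backbone_depth,
    base_channels = base_channels, fpn_channels = fpn_channels,
    roi_output_size = roi_output_size,
    mask_resolution = as.integer(mask_resolution),
    num_classes = 5L, classes = c("background", ANATOMY_CLASSES),
    pyramid_levels = levels,
    anchor_ratios = anchor_ratios,
    anchor_scales = lapply(levels, function(s) 4 * s * 2^((0:2) / 3)),
    anchors_per_cell = 3L * length(anchor_ratios),
    proposals_per_image = proposals_per_image,
    seed = as.integer(seed)), class = "model_config")
}

#' Create a randomly initialized model
#'
#' Weights are He-uniform, drawn under `config$seed`, so two calls with the
#' same config produce identical models.  No pretrained weights are used.
#'
#' @param config A [model_config()].
#' @return An object of class `insect_model` (list of `params` and `config`).
#' @export
new_model <- function(config = model_config()) {
  F <- config$fpn_channels
  A <- config$anchors_per_cell
  nl <- length(config$pyramid_levels)
  with_seed(config$seed, {
    chans <- c(config$base_channels, 2 * config$base_channels)
    p <- list(stem1 = conv_param(3, chans[1], 3, 2L),
              stem2 = conv_param(chans[1], chans[2], 3, 2L))
    cin <- chans[2]
    stage_ch <- cin
    for (i in seq_len(config$backbone_depth)) {
      cout <- 2 * config$base_channels + 8L * i
      p[[paste0("down", i)]] <- conv_param(cin, cout, 3, 2L)
      p[[paste0("res", i, "a")]] <- conv_param(cout, cout, 3, 1L)
      p[[paste0("res", i, "b")]] <- conv_param(cout, cout, 3, 1L)
      cin <- cout
      stage_ch <- c(stage_ch, cout)
    }
    for (l in seq_len(nl)) {
      p[[paste0("lat", l)]] <- conv_param(stage_ch[l], F, 1, 1L)
      p[[paste0("smooth", l)]] <- conv_param(F, F, 3, 1L)
    }
    p$rpn_conv <- conv_param(F, F, 3, 1L)
    p$rpn_cls <- conv_param(F, 2L * A, 1, 1L)
    p$rpn_reg <- conv_param(F, 4L * A, 1, 1L)
    p$fc1 <- dense_param(F * config$roi_output_size^2, 64)
    p$fc_cls <- dense_param(64, config$num_classes)
    p$fc_reg <- dense_param(64, 4)
    p$mc1 <- conv_param(F + 3, F, 3, 1L)
    p$mc2 <- conv_param(F, F, 3, 1L)
    p$mc3 <- conv_param(F, 4, 1, 1L)
    structure(list(params = p, config = config), class = "insect_model")
  })
}

#' @export
print.insect_model <- function(x, ...) {
  np <- sum(rapply(x$params, function(v) if (is.numeric(v)) length(v) else 0L,
                   how = "unlist"))
  cat(sprintf("<insect_model: %d-stage backbone, strides %s, %d parameters>\n",
              x$config$backbone_depth,
              paste(x$config$pyramid_levels, collapse = "/"), np))
  invisible(x)
}

# Normalize raw integer pixels to the network input range.
input_tensor <- function(pixels) {
  array(pixels / 255 - 0.5, dim = dim(pixels))
}

# Backbone + FPN forward; returns pyramid (finest first) and a cache for the
# backward pass.
trunk_fwd <- function(model, x0) {
  p <- model$params
  depth <- model$config$backbone_depth
  cache <- list(x0 = x0)
  s1 <- relu(conv_fwd(p$stem1, x0))
  s2 <- relu(conv_fwd(p$stem2, s1))
  cache$s1 <- s1
  cache$s2 <- s2
  C <- list(s2)
  prev <- s2
  for (i in seq_len(depth)) {
    h <- relu(conv_fwd(p[[paste0("down", i)]], prev))
    r1 <- relu(conv_fwd(p[[paste0("res", i, "a")]], h))
    r2 <- conv_fwd(p[[paste0("res", i, "b")]], r1)
    o <- relu(h + r2)
    cache[[paste0("h", i)]] <- h
    cache[[paste0("r1_", i)]] <- r1
    cache[[paste0("o", i)]] <- o
    C <- c(C, list(o))
    prev <- o
  }
  nl <- length(C)
  lat <- vector("list", nl)
  for (l in seq_len(nl)) lat[[l]] <- conv_fwd(p[[paste0("lat", l)]], C[[l]])
  M <- vector("list", nl)
  M[[nl]] <- lat[[nl]]
  for (l in rev(seq_len(nl - 1))) M[[l]] <- lat[[l]] + .nn_upsample2_fwd(M[[l + 1]])
  P <- vector("list", nl)
  for (l in seq_len(nl)) P[[l]] <- conv_fwd(p[[paste0("smooth", l)]], M[[l]])
  cache$C <- C
  cache$M <- M
  list(P = P, cache = cache)
}

trunk_bwd <- function(model, cache, dP) {
  p <- model$params
  depth <- model$config$backbone_depth
  nl <- length(cache$C)
  g <- list()
  dM <- vector("list", nl)
  for (l in seq_len(nl)) {
    r <- conv_bwd(p[[paste0("smooth", l)]], cache$M[[l]], dP[[l]])
    g[[paste0("smooth", l)]] <- list(w = r$dw, b = r$db)
    dM[[l]] <- r$dx
  }
  dC <- vector("list", nl)
  for (l in seq_len(nl)) {
    if (l > 1) dM[[l]] <- dM[[l]] + .nn_upsample2_bwd(dM[[l - 1]])
    r <- conv_bwd(p[[paste0("lat", l)]], cache$C[[l]], dM[[l]])
    g[[paste0("lat", l)]] <- list(w = r$dw, b = r$db)
    dC[[l]] <- r$dx
  }
  dprev <- NULL
  for (i in rev(seq_len(depth))) {
    do <- dC[[i + 1]]
    if (!is.null(dprev)) do <- do + dprev
    o <- cache[[paste0("o", i)]]
    h <- cache[[paste0("h", i)]]
    r1 <- cache[[paste0("r1_", i)]]
    dpre <- relu_bwd(o, do)
    rb <- conv_bwd(p[[paste0("res", i, "b")]], r1, dpre)
    g[[paste0("res", i, "b")]] <- list(w = rb$dw, b = rb$db)
    dr1 <- relu_bwd(r1, rb$dx)
    ra <- conv_bwd(p[[paste0("res", i, "a")]], h, dr1)
    g[[paste0("res", i, "a")]] <- list(w = ra$dw, b = ra$db)
    dh <- dpre + ra$dx
    dh <- relu_bwd(h, dh)
    prev <- if (i == 1) cache$s2 else cache[[paste0("o", i - 1)]]
    rd <- conv_bwd(p[[paste0("down", i)]], prev, dh)
    g[[paste0("down", i)]] <- list(w = rd$dw, b = rd$db)
    dprev <- rd$dx
  }
  ds2 <- dC[[1]]
  if (!is.null(dprev)) ds2 <- ds2 + dprev
  ds2 <- relu_bwd(cache$s2, ds2)
  r2 <- conv_bwd(p$stem2, cache$s1, ds2)
  g$stem2 <- list(w = r2$dw, b = r2$db)
  ds1 <- relu_bwd(cache$s1, r2$dx)
  r1 <- conv_bwd(p$stem1, cache$x0, ds1)
  g$stem1 <- list(w = r1$dw, b = r1$db)
  g
}

rpn_fwd <- function(model, P) {
  p <- model$params
  lapply(P, function(feat) {
    t <- relu(conv_fwd(p$rpn_conv, feat))
    list(t = t, cls = conv_fwd(p$rpn_cls, t), reg = conv_fwd(p$rpn_reg, t))
  })
}

rpn_bwd <- function(model, P, rpn_out, dcls, dreg) {
  p <- model$params
  g <- NULL
  dP <- vector("list", length(P))
  for (l in seq_along(P)) {
    t <- rpn_out[[l]]$t
    rc <- conv_bwd(p$rpn_cls, t, dcls[[l]])
    rr <- conv_bwd(p$rpn_reg, t, dreg[[l]])
    dt <- relu_bwd(t, rc$dx + rr$dx)
    rt <- conv_bwd(p$rpn_conv, P[[l]], dt)
    dP[[l]] <- rt$dx
    g <- acc_grads(g, list(rpn_cls = list(w = rc$dw, b = rc$db),
                           rpn_reg = list(w = rr$dw, b = rr$db),
                           rpn_conv = list(w = rt$dw, b = rt$db)))
  }
  list(grads = g, dP = dP)
}

#' Extract the feature pyramid for an image
#'
#' Runs the residual backbone and feature pyramid in inference mode.
#'
#' @param model An [new_model()] object.
#' @param pixels `H x W x 3` integer array in `[0, 255]`, `H = W =`
#'   `config$image_size`.
#' @return An `insect_features` object: `P`, the list of feature cubes
#'   (finest level first; level `l` has spatial side `image_size / stride_l`
#'   and `fpn_channels` channels), and `x0`, the normalized input tensor
#'   the mask head samples for pixel-level detail.
#' @export
extract_features <- function(model, pixels) {
  d <- dim(pixels)
  if (d[1] != d[2] || d[1] != model$config$image_size)
    stop("image must be square and match config$image_size")
  x0 <- input_tensor(pixels)
  structure(list(P = trunk_fwd(model, x0)$P, x0 = x0),
            class = "insect_features")
}

# FPN level assignment for an RoI: floor(l0 + log2(sqrt(wh)/canonical)),
# clamped to the available levels.  Canonical size 4 * stride of level l0.
roi_level <- function(config, w, h) {
  nl <- length(config$pyramid_levels)
  l0 <- min(2L, nl)
  canonical <- 4 * config$pyramid_levels[l0]
  clamp(floor(l0 + log2(pmax(sqrt(w * h), 1) / canonical)), 1, nl)
}

#' RoI-align a box onto the feature pyramid
#'
#' Bilinearly samples a fixed-size patch from the pyramid level selected by
#' box size (larger boxes map to coarser levels, monotonically).  No
#' coordinate quantization takes place: the box is used in continuous
#' feature-map coordinates with 2x2 samples per output bin.
#'
#' @param model An `insect_model`.
#' @param features Pyramid from [extract_features()].
#' @param b A one-row box data frame in image coordinates.
#' @param out_size Output side in cells (default `config$roi_output_size`).
#' @param sampling Bilinear samples per bin side (2 in the trained pipeline;
#'   1 samples exactly at bin centers, so a box aligned to the feature grid
#'   reproduces the direct crop).
#' @return `out_size x out_size x fpn_channels` array.
#' @export
align_roi <- function(model, features, b, out_size = NULL, sampling = 2L) {
  if (b$w <= 0 || b$h <= 0) stop("degenerate box")
  if (inherits(features, "insect_features")) features <- features$P
  out_size <- out_size %||% model$config$roi_output_size
  lv <- roi_level(model$config, b$w, b$h)
  s <- model$config$pyramid_levels[lv]
  .nn_roi_align_fwd(features[[lv]], b$x / s, b$y / s, b$w / s, b$h / s,
                    out_size, as.integer(sampling))
}

head_fwd <- function(model, patch) {
  p <- model$params
  x <- as.numeric(patch)
  h1p <- dense_fwd(p$fc1, x)
  h1 <- pmax(h1p, 0)
  list(x = x, h1 = h1,
       logits = dense_fwd(p$fc_cls, h1),
       delta = dense_fwd(p$fc_reg, h1))
}

head_bwd <- function(model, cache, dlogits, ddelta) {
  p <- model$params
  rc <- dense_bwd(p$fc_cls, cache$h1, dlogits)
  rr <- dense_bwd(p$fc_reg, cache$h1, ddelta)
  dh1 <- rc$dx + rr$dx
  dh1[cache$h1 <= 0] <- 0
  r1 <- dense_bwd(p$fc1, cache$x, dh1)
  list(grads = list(fc_cls = list(w = rc$dw, b = rc$db),
                    fc_reg = list(w = rr$dw, b = rr$db),
                    fc1 = list(w = r1$dw, b = r1$db)),
       dpatch = r1$dx)
}

# Mask-head input: RoI-aligned pyramid features concatenated with the
# RoI-aligned raw image, both at mask_resolution.
mask_patch <- function(model, features, b) {
  cf <- model$config
  n <- cf$mask_resolution
  lv <- roi_level(cf, b$w, b$h)
  s <- cf$pyramid_levels[lv]
  fp <- .nn_roi_align_fwd(features$P[[lv]], b$x / s, b$y / s, b$w / s,
                          b$h / s, n, 2L)
  ip <- .nn_roi_align_fwd(features$x0, b$x, b$y, b$w, b$h, n, 2L)
  out <- array(0, c(n, n, cf$fpn_channels + 3L))
  out[, , seq_len(cf$fpn_channels)] <- fp
  out[, , cf$fpn_channels + (1:3)] <- ip
  out
}

mask_fwd <- function(model, patch) {
  p <- model$params
  m1 <- relu(conv_fwd(p$mc1, patch))
  m2 <- relu(conv_fwd(p$mc2, m1))
  list(patch = patch, m1 = m1, m2 = m2,
       logits = conv_fwd(p$mc3, m2))
}

mask_bwd <- function(model, cache, dlogits) {
  p <- model$params
  r3 <- conv_bwd(p$mc3, cache$m2, dlogits)
  dm2 <- relu_bwd(cache$m2, r3$dx)
  r2 <- conv_bwd(p$mc2, cache$m1, dm2)
  dm1 <- relu_bwd(cache$m1, r2$dx)
  r1 <- conv_bwd(p$mc1, cache$patch, dm1)
  list(grads = list(mc3 = list(w = r3$dw, b = r3$db),
                    mc2 = list(w = r2$dw, b = r2$db),
                    mc1 = list(w = r1$dw, b = r1$db)),
       dpatch = r1$dx)
}

#' Run the three parallel heads on an aligned patch
#'
#' @param model An `insect_model`.
#' @param features Pyramid from [extract_features()].
#' @param b One-row box data frame (the RoI, image coordinates).
#' @return List: `probs` (5 class probabilities summing to 1, background
#'   first), `delta` (one-row box-delta data frame), `mask_logits`
#'   (`mask_resolution^2 x 4` cube, one channel per anatomy class).
#' @export
run_heads <- function(model, features, b) {
  patch <- align_roi(model, features, b)
  hd <- head_fwd(model, patch)
  mk <- mask_fwd(model, mask_patch(model, features, b))
  list(probs = softmax(hd$logits),
       delta = data.frame(tx = hd$delta[1], ty = hd$delta[2],
                          tw = hd$delta[3], th = hd$delta[4]),
       mask_logits = mk$logits)
}

# Anchor table matching the RPN output channel layout for this config.
model_anchors <- function(config) {
  make_anchors(config$image_size, config$pyramid_levels,
               config$anchor_scales, config$anchor_ratios)
}

# Per-level anchor counts, in the same order as model_anchors rows.
anchors_per_level <- function(config) {
  vapply(config$pyramid_levels,
         function(s) (config$image_size %/% s)^2 * config$anchors_per_cell,
         numeric(1))
}

# Extract per-anchor foreground scores and deltas from raw RPN cubes, in
# model_anchors row order (grid-row, grid-col, variant; level blocks).
rpn_flatten <- function(config, rpn_out) {
  A <- config$anchors_per_cell
  scores <- numeric(0)
  deltas <- NULL
  for (l in seq_along(rpn_out)) {
    cls <- rpn_out[[l]]$cls
    reg <- rpn_out[[l]]$reg
    bg <- as.numeric(cls[, , 2 * (1:A) - 1])
    fg <- as.numeric(cls[, , 2 * (1:A)])
    m <- pmax(bg, fg)
    scores <- c(scores, exp(fg - m) / (exp(bg - m) + exp(fg - m)))
    d <- data.frame(tx = as.numeric(reg[, , 4 * (1:A) - 3]),
                    ty = as.numeric(reg[, , 4 * (1:A) - 2]),
                    tw = as.numeric(reg[, , 4 * (1:A) - 1]),
                    th = as.numeric(reg[, , 4 * (1:A)]))
    deltas <- rbind(deltas, d)
  }
  list(scores = scores, deltas = deltas)
}

#' Generate region proposals for an image
#'
#' Decodes the proposal stage's per-anchor objectness and box deltas, clips
#' boxes to the image, applies greedy non-maximum suppression and keeps the
#' top-scoring survivors.
#'
#' @param model An `insect_model`.
#' @param features Pyramid from [extract_features()].
#' @param pre_nms Candidates kept before suppression.
#' @param nms_thr Suppression IoU threshold.
#' @return Box data frame with a `score` column, at most
#'   `config$proposals_per_image` rows.
#' @export
propose <- function(model, features, pre_nms = 768, nms_thr = 0.8) {
  config <- model$config
  if (inherits(features, "insect_features")) features <- features$P
  rpn_out <- rpn_fwd(model, features)
  fl <- rpn_flatten(config, rpn_out)
  anchors <- model_anchors(config)
  boxes <- decode_boxes(fl$deltas, anchors, max_dim = 10 * sqrt(2) * config$image_size)
  x2 <- clamp(boxes$x + boxes$w, 0, config$image_size)
  y2 <- clamp(boxes$y + boxes$h, 0, config$image_size)
  boxes$x <- clamp(boxes$x, 0, config$image_size)
  boxes$y <- clamp(boxes$y, 0, config$image_size)
  boxes$w <- x2 - boxes$x
  boxes$h <- y2 - boxes$y
  ok <- which(boxes$w >= 1 & boxes$h >= 1)
  ord <- ok[order(fl$scores[ok], decreasing = TRUE)]
  ord <- ord[seq_len(min(pre_nms, length(ord)))]
  cand <- boxes[ord, , drop = FALSE]
  sc <- fl$scores[ord]
  keep <- nms(cand, sc, nms_thr)
  keep <- keep[seq_len(min(config$proposals_per_image, length(keep)))]
  out <- cand[keep, , drop = FALSE]
  out$score <- sc[keep]
  rownames(out) <- NULL
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding both parameters and config.
#'
#' @param model An `insect_model`.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "insect_model")) stop("not an insect_model checkpoint: ", path)
  m
}
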