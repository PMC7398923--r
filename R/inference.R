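#' Detect anatomical components in an image
#'
#' Runs the full pipeline: feature pyramid, region proposals, the three
#' parallel heads, per-class non-maximum suppression on the tightened boxes,
#' and upsampling of the predicted low-resolution masks to full image
#' resolution.  Deterministic given the model and thresholds.
#'
#' @param image An [annotated_image()] (pixels required) or a raw
#'   `H x W x 3` array; resized to the model's input size if needed.
#' @param model An `insect_model`, an `insect_fit`, or a checkpoint path.
#' @param score_thr Minimum class confidence for a detection.
#' @param nms_thr Per-class suppression IoU threshold.
#' @param mask_thr Binarization threshold for mask probabilities.
#' @param per_class_cap Optional named vector limiting detections per class,
#'   e.g. `c(thorax = 1, abdomen = 1, wing = 4, leg = 8)`; `NULL` = no cap.
#' @return List of `detection` objects (label, score, box, full-resolution
#'   logical mask), sorted by decreasing score.
#' @export
detect <- function(image, model, score_thr = 0.5, nms_thr = 0.5,
                   mask_thr = 0.5, per_class_cap = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "insect_fit")) model <- model$model
  stopifnot(inherits(model, "insect_model"))
  if (any(c(score_thr, nms_thr, mask_thr) < 0) ||
      any(c(score_thr, nms_thr, mask_thr) > 1))
    stop("thresholds must lie in [0, 1]")
  if (is.array(image)) image <- annotated_image("image", dim(image)[2],
                                                dim(image)[1], image)
  S <- model$config$image_size
  image <- preprocess(image, S)
  features <- extract_features(model, image$pixels)
  props <- suppressWarnings(propose(model, features))
  clip_box <- function(rb) {
    x2 <- clamp(rb$x + rb$w, 0, S); y2 <- clamp(rb$y + rb$h, 0, S)
    rb$x <- clamp(rb$x, 0, S); rb$y <- clamp(rb$y, 0, S)
    rb$w <- x2 - rb$x; rb$h <- y2 - rb$y
    rb
  }
  cand <- list()
  for (k in seq_len(nrow(props))) {
    b <- props[k, c("x", "y", "w", "h")]
    hd <- run_heads(model, features, b)
    ci <- which.max(hd$probs)
    if (ci == 1) next                     # background
    score <- hd$probs[ci]
    if (score < score_thr) next
    rb <- clip_box(decode_boxes(hd$delta, b))
    if (rb$w < 1 || rb$h < 1) next
    cand <- c(cand, list(list(label = ANATOMY_CLASSES[ci - 1], score = score,
                              class_index = ci, box = rb)))
  }
  out <- list()
  for (cl in ANATOMY_CLASSES) {
    idx <- which(vapply(cand, function(d) d$label == cl, TRUE))
    if (!length(idx)) next
    boxes <- do.call(rbind, lapply(cand[idx], `[[`, "box"))
    scores <- vapply(cand[idx], `[[`, 0, "score")
    keep <- nms(boxes, scores, nms_thr)
    if (!is.null(per_class_cap) && cl %in% names(per_class_cap))
      keep <- keep[seq_len(min(per_class_cap[[cl]], length(keep)))]
    for (k in keep) {
      d <- cand[[idx[k]]]
      # the mask is predicted on the tightened box, so pixels and box agree
      mk <- mask_fwd(model, mask_patch(model, features, d$box))
      mask <- paste_mask(mk$logits[, , d$class_index - 1L], d$box, S, mask_thr)
      out <- c(out, list(structure(list(label = d$label, score = d$score,
                                        box = d$box, mask = mask),
                                   class = "detection")))
    }
  }
  out[order(vapply(out, `[[`, 0, "score"), decreasing = TRUE)]
}

# Upsample mask logits into the box footprint of a full-resolution canvas.
paste_mask <- function(mlog, b, S, mask_thr) {
  mask <- matrix(FALSE, S, S)
  c0 <- clamp(floor(b$x) + 1, 1, S); c1 <- clamp(ceiling(b$x + b$w), 1, S)
  r0 <- clamp(floor(b$y) + 1, 1, S); r1 <- clamp(ceiling(b$y + b$h), 1, S)
  if (c1 < c0 || r1 < r0) return(mask)
  pr <- sigmoid(.nn_bilinear_resize(array(mlog, c(dim(mlog), 1)),
                                    r1 - r0 + 1, c1 - c0 + 1)[, , 1])
  mask[r0:r1, c0:c1] <- pr > mask_thr
  mask
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection %s score=%.3f box=(%.1f,%.1f,%.1f,%.1f) mask=%d px>\n",
              x$label, x$score, x$box$x, x$box$y, x$box$w, x$box$h,
              sum(x$mask)))
  invisible(x)
}

#' Write per-detection anatomy cut-outs
#'
#' For each detection the source pixels under its mask are written as an
#' RGBA PNG cropped to the detection box: masked pixels are opaque, the rest
#' transparent.  Files are named `{image_id}_{label}_{k}.png`.
#'
#' @param image The [annotated_image()] the detections came from (at the
#'   same resolution as the masks).
#' @param detections List of detections from [detect()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
extract_anatomy <- function(image, detections, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sub("\\.(png|jpg|jpeg)$", "", image$image_id, ignore.case = TRUE)
  counts <- structure(integer(length(ANATOMY_CLASSES)),
                      names = ANATOMY_CLASSES)
  paths <- character(0)
  for (d in detections) {
    counts[d$label] <- counts[d$label] + 1L
    b <- d$box
    c0 <- clamp(floor(b$x) + 1, 1, image$width)
    c1 <- clamp(ceiling(b$x + b$w), 1, image$width)
    r0 <- clamp(floor(b$y) + 1, 1, image$height)
    r1 <- clamp(ceiling(b$y + b$h), 1, image$height)
    crop <- image$pixels[r0:r1, c0:c1, , drop = FALSE] / 255
    alpha <- (d$mask[r0:r1, c0:c1, drop = FALSE]) * 1
    rgba <- array(0, c(dim(alpha), 4))
    rgba[, , 1:3] <- crop
    rgba[, , 4] <- alpha
    path <- file.path(out_dir, sprintf("%s_%s_%d.png", stem, d$label,
                                       counts[d$label]))
    png::writePNG(rgba, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
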