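#' Instance matching at an IoU threshold
#'
#' Greedy matching in decreasing score order: each detection is matched to
#' its best-overlapping, still unmatched ground truth of the same class; it
#' is a true positive when that IoU reaches `iou_thr`, otherwise a false
#' positive.  Unmatched ground truths are false negatives.  Overlap is
#' computed on masks (`iou_kind = "mask"`, the default: the goal is pixel
#' extraction) or on boxes.
#'
#' @param detections List of `detection` objects (one image, one class).
#' @param gt List with `boxes` (data frame) and `masks` (list), the ground
#'   truth of the same image and class.
#' @param iou_thr Matching threshold in `[0, 1]`.
#' @param iou_kind `"mask"` or `"box"`.
#' @return List: `tp`, `fp`, `fn`, `match` (per-detection gt index, NA for
#'   false positives), `det_iou` (per-detection matched IoU).
#' @export
match_instances <- function(detections, gt, iou_thr, iou_kind = c("mask", "box")) {
  iou_kind <- match.arg(iou_kind)
  scores <- vapply(detections, `[[`, 0, "score")
  ord <- order(scores, decreasing = TRUE)
  ngt <- if (is.null(gt$boxes)) 0L else nrow(gt$boxes)
  taken <- rep(FALSE, ngt)
  match <- rep(NA_integer_, length(detections))
  det_iou <- rep(0, length(detections))
  for (k in ord) {
    if (ngt == 0) break
    d <- detections[[k]]
    ovs <- vapply(seq_len(ngt), function(g) {
      if (taken[g]) return(-1)
      if (iou_kind == "box") iou(d$box, gt$boxes[g, , drop = FALSE])
      else {
        if (!any(d$mask) && !any(gt$masks[[g]])) return(-1)
        if (!any(d$mask) || !any(gt$masks[[g]])) return(0)
        iou(d$mask, gt$masks[[g]])
      }
    }, 0)
    best <- which.max(ovs)
    if (length(best) && ovs[best] >= iou_thr) {
      taken[best] <- TRUE
      match[k] <- best
      det_iou[k] <- ovs[best]
    }
  }
  tp <- sum(!is.na(match))
  list(tp = tp, fp = length(detections) - tp, fn = ngt - tp,
       match = match, det_iou = det_iou)
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`.  An undefined
#' ratio (zero denominator) is reported as `NA`, never silently as 0 or 1.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `c(precision, recall)` (NA when undefined).
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Average precision for one class at one IoU threshold
#'
#' Sweeps the score-ranked detection list over all images, accumulating
#' true/false positives, and integrates the precision-recall curve with
#' 101-point interpolation: the precision at recall `r` is the maximum
#' precision attained at any recall at or above it, averaged over the 101
#' recall values 0, 0.01, ..., 1.
#'
#' @param detections Named list (by image id) of detection lists, already
#'   restricted to one class.
#' @param gts Named list (by image id) of ground truth (`boxes`, `masks`)
#'   restricted to the same class.
#' @param iou_thr Matching threshold.
#' @param iou_kind `"mask"` or `"box"`.
#' @return AP in `[0, 1]`, or `NA` if the class has no ground truth.
#' @export
average_precision <- function(detections, gts, iou_thr,
                              iou_kind = c("mask", "box")) {
  iou_kind <- match.arg(iou_kind)
  n_gt <- sum(vapply(gts, function(g) if (is.null(g$boxes)) 0L else nrow(g$boxes), 0L))
  if (n_gt == 0) return(NA_real_)
  scores <- numeric(0)
  is_tp <- logical(0)
  for (id in names(gts)) {
    dets <- detections[[id]] %||% list()
    m <- match_instances(dets, gts[[id]], iou_thr, iou_kind)
    scores <- c(scores, vapply(dets, `[[`, 0, "score"))
    is_tp <- c(is_tp, !is.na(m$match))
  }
  if (length(scores) == 0) return(0)
  ord <- order(scores, decreasing = TRUE)
  tp_cum <- cumsum(is_tp[ord])
  fp_cum <- cumsum(!is_tp[ord])
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / n_gt
  interp_ap(prec, rec)
}

interp_ap <- function(prec, rec) {
  grid <- seq(0, 1, by = 0.01)
  mean(vapply(grid, function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[ok]) else 0
  }, 0))
}

#' Mean average precision over the four anatomy classes
#'
#' @param per_class_aps Numeric vector of per-class APs; `NA` entries
#'   (classes without ground truth) are excluded with a warning.
#' @return Arithmetic mean of the available APs.
#' @export
mean_average_precision <- function(per_class_aps) {
  if (all(is.na(per_class_aps))) stop("no class has a defined AP")
  if (any(is.na(per_class_aps)))
    warning("excluding classes without ground truth from mAP")
  mean(per_class_aps, na.rm = TRUE)
}

#' Evaluate detections over a dataset
#'
#' Aggregates TP/FP/FN over all images per class (micro-averaging) before
#' computing precision and recall at each IoU threshold, computes per-class
#' AP and mAP, and optionally per-class pixel-level precision/recall of the
#' union of predicted vs ground-truth masks.
#'
#' @param detections Named list (image id -> list of detections).
#' @param gts Named list (image id -> list with `gt_boxes`/`boxes`,
#'   `gt_labels`/`labels`, `masks`), e.g. from [image_ground_truth()].
#' @param thresholds IoU thresholds, default `c(0.30, 0.50, 0.70)`.
#' @param iou_kind `"mask"` (default) or `"box"`.
#' @param pixel_level Also compute pixel-level precision/recall per class.
#' @return An `eval_report`: `per_class` data frame (`class, iou_thr,
#'   tp, fp, fn, precision, recall, ap` -- precision/recall in percent),
#'   `map_by_iou` named list, and optionally `pixel` data frame.
#' @export
evaluate_dataset <- function(detections, gts, thresholds = c(0.3, 0.5, 0.7),
                             iou_kind = c("mask", "box"), pixel_level = FALSE) {
  iou_kind <- match.arg(iou_kind)
  ids_d <- names(detections); ids_g <- names(gts)
  if (!setequal(ids_d, ids_g))
    stop("image_id mismatch between detections and ground truth: ",
         paste(c(setdiff(ids_d, ids_g), setdiff(ids_g, ids_d)), collapse = ", "))
  norm_gt <- lapply(gts, function(g) {
    list(boxes = g$boxes %||% g$gt_boxes,
         labels = g$labels %||% g$gt_labels,
         masks = g$masks)
  })
  by_class <- function(g, cl) {
    sel <- which(g$labels == cl)
    list(boxes = if (length(sel)) g$boxes[sel, , drop = FALSE] else NULL,
         masks = g$masks[sel])
  }
  rows <- NULL
  map_by_iou <- list()
  for (thr in thresholds) {
    aps <- numeric(0)
    for (cl in ANATOMY_CLASSES) {
      gcl <- lapply(norm_gt, by_class, cl = cl)
      dcl <- lapply(ids_g, function(id) {
        dd <- detections[[id]] %||% list()
        dd[vapply(dd, function(d) d$label == cl, TRUE)]
      })
      names(dcl) <- ids_g
      tp <- 0L; fp <- 0L; fn <- 0L
      for (id in ids_g) {
        m <- match_instances(dcl[[id]], gcl[[id]], thr, iou_kind)
        tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
      }
      pr <- precision_recall(tp, fp, fn)
      ap <- average_precision(dcl, gcl, thr, iou_kind)
      aps[cl] <- ap
      rows <- rbind(rows, data.frame(class = cl, iou_thr = thr, tp = tp,
                                     fp = fp, fn = fn,
                                     precision = 100 * pr[["precision"]],
                                     recall = 100 * pr[["recall"]],
                                     ap = ap))
    }
    map_by_iou[[format(thr)]] <- mean_average_precision(aps)
  }
  rownames(rows) <- NULL
  out <- list(per_class = rows, map_by_iou = map_by_iou, iou_kind = iou_kind)
  if (pixel_level) {
    prow <- NULL
    for (cl in ANATOMY_CLASSES) {
      tp <- 0; fp <- 0; fn <- 0
      for (id in ids_g) {
        g <- norm_gt[[id]]
        sel <- which(g$labels == cl)
        gm <- Reduce(`|`, g$masks[sel], accumulate = FALSE) %||% NULL
        dd <- detections[[id]] %||% list()
        dm <- NULL
        for (d in dd) if (d$label == cl) dm <- if (is.null(dm)) d$mask else dm | d$mask
        if (is.null(gm) && is.null(dm)) next
        if (is.null(gm)) { fp <- fp + sum(dm); next }
        if (is.null(dm)) { fn <- fn + sum(gm); next }
        tp <- tp + sum(dm & gm); fp <- fp + sum(dm & !gm); fn <- fn + sum(!dm & gm)
      }
      pr <- precision_recall(tp, fp, fn)
      prow <- rbind(prow, data.frame(class = cl,
                                     precision = 100 * pr[["precision"]],
                                     recall = 100 * pr[["recall"]]))
    }
    out$pixel <- prow
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(format_eval_report(x), sep = "\n")
  invisible(x)
}

#' Render an evaluation report as text tables
#'
#' One row per anatomy class with precision/recall columns per IoU
#' threshold, followed by an mAP table per threshold.
#'
#' @param report An `eval_report` from [evaluate_dataset()].
#' @return Character vector of lines.
#' @export
format_eval_report <- function(report) {
  pc <- report$per_class
  thrs <- sort(unique(pc$iou_thr))
  hdr <- paste0("Anatomy   ", paste(sprintf("IoU=%.2f  Prec(%%)  Rec(%%)", thrs),
                                    collapse = "   "))
  lines <- c(hdr)
  for (cl in ANATOMY_CLASSES) {
    cells <- vapply(thrs, function(t) {
      r <- pc[pc$class == cl & pc$iou_thr == t, ]
      sprintf("          %7s  %6s",
              ifelse(is.na(r$precision), "n/a", sprintf("%.2f", r$precision)),
              ifelse(is.na(r$recall), "n/a", sprintf("%.2f", r$recall)))
    }, "")
    lines <- c(lines, sprintf("%-9s %s", cl, paste(cells, collapse = "  ")))
  }
  lines <- c(lines, "", "mAP by IoU threshold:")
  for (t in names(report$map_by_iou))
    lines <- c(lines, sprintf("  IoU=%s  mAP=%.4f (%.2f%%)", t,
                              report$map_by_iou[[t]], 100 * report$map_by_iou[[t]]))
  if (!is.null(report$pixel)) {
    lines <- c(lines, "", "Pixel-level precision/recall (%):")
    for (k in seq_len(nrow(report$pixel)))
      lines <- c(lines, sprintf("  %-9s P=%6s R=%6s", report$pixel$class[k],
                                sprintf("%.2f", report$pixel$precision[k]),
                                sprintf("%.2f", report$pixel$recall[k])))
  }
  lines
}

#' Write an evaluation report as CSV
#' @param report An `eval_report`.
#' @param path Output CSV path (per-class table; mAP rows appended with
#'   class `"mAP"`).
#' @export
write_eval_report <- function(report, path) {
  pc <- report$per_class
  for (t in names(report$map_by_iou))
    pc <- rbind(pc, data.frame(class = "mAP", iou_thr = as.numeric(t),
                               tp = NA, fp = NA, fn = NA, precision = NA,
                               recall = NA, ap = report$map_by_iou[[t]]))
  write.csv(pc, path, row.names = FALSE)
  invisible(path)
}
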