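# Detection post-processing and metrics: raw-head decoding, greedy NMS,
# greedy TP/FP/FN matching, precision/recall/F1, average precision by
# all-point interpolation of the precision-recall curve, AP50:95, and
# stratified reporting by size / illumination / viewpoint tags.

#' Decode raw head outputs and apply non-maximum suppression
#'
#' Grid and anchor offsets are decoded to normalized center-format boxes
#' (`xy = (2 * sigmoid(t) - 0.5 + grid) * stride`,
#' `wh = (2 * sigmoid(t))^2 * anchor`), confidences below the confidence
#' threshold are removed, and greedy class-agnostic NMS suppresses any box
#' overlapping a kept higher-confidence box beyond the IoU threshold.
#'
#' @param raw list of three raw head outputs (tg nodes or arrays).
#' @param cfg the `pn_config` of the detector that produced `raw`.
#' @param conf_threshold minimum confidence (objectness x class), default 0.25.
#' @param iou_threshold NMS overlap threshold, default 0.5.
#' @param input_size pixels.
#' @return `pn_boxes` tibble with `conf`, sorted by descending confidence.
#' @export
decode_and_nms <- function(raw, cfg, conf_threshold = 0.25,
                           iou_threshold = 0.5,
                           input_size = cfg$input_size) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1,
            iou_threshold >= 0, iou_threshold <= 1)
  nc <- cfg$num_classes
  nf <- 5L + nc
  strides <- c(8L, 16L, 32L)
  scale_f <- input_size / 640
  all <- list()
  for (si in 1:3) {
    x <- tg_value(raw[[si]])
    d <- dim(x)
    ng_h <- d[2]; ng_w <- d[3]
    dim(x) <- c(nf, 3L, ng_h, ng_w)
    anch <- cfg$anchors[[si]] * scale_f           # pixels
    s <- strides[si]
    sl <- function(k) array(x[k, , , ], c(3L, ng_h, ng_w))
    tx <- stats::plogis(sl(1)); ty <- stats::plogis(sl(2))
    tw <- stats::plogis(sl(3)); th <- stats::plogis(sl(4))
    obj <- stats::plogis(sl(5))
    gi <- array(rep(rep(seq_len(ng_w) - 1L, each = 3L * ng_h)), c(3L, ng_h, ng_w))
    gj <- array(rep(rep(seq_len(ng_h) - 1L, each = 3L), ng_w), c(3L, ng_h, ng_w))
    aw <- array(anch[, 1], c(3L, ng_h, ng_w))
    ah <- array(anch[, 2], c(3L, ng_h, ng_w))
    cx <- (2 * tx - 0.5 + gi) * s / input_size
    cy <- (2 * ty - 0.5 + gj) * s / input_size
    w <- (2 * tw)^2 * aw / input_size
    h <- (2 * th)^2 * ah / input_size
    cls_p <- array(1, c(3L, ng_h, ng_w)); cls_id <- array(0L, c(3L, ng_h, ng_w))
    if (nc >= 1) {
      cl <- array(stats::plogis(x[5L + seq_len(nc), , , ]),
                  c(nc, 3L * ng_h * ng_w))
      cls_p <- apply(cl, 2, max)
      cls_id <- max.col(t(cl)) - 1L
    }
    conf <- as.vector(obj) * as.vector(cls_p)
    keep <- which(conf >= conf_threshold)
    if (length(keep)) {
      all[[si]] <- tibble::tibble(
        class_id = as.integer(cls_id)[keep],
        cx = as.vector(cx)[keep], cy = as.vector(cy)[keep],
        w = as.vector(w)[keep], h = as.vector(h)[keep],
        conf = conf[keep])
    }
  }
  dets <- if (length(all)) dplyr::bind_rows(all) else
    tibble::tibble(class_id = integer(), cx = numeric(), cy = numeric(),
                   w = numeric(), h = numeric(), conf = numeric())
  dets <- dets[order(-dets$conf), ]
  b <- bbox_tibble(dets$class_id, dets$cx, dets$cy, dets$w, dets$h, dets$conf)
  nms_boxes(b, iou_threshold)
}

#' Greedy non-maximum suppression
#'
#' @param boxes `pn_boxes` with confidences.
#' @param iou_threshold boxes with IoU strictly above this against a kept box
#'   are suppressed.
#' @return the kept subset, sorted by descending confidence.
#' @export
nms_boxes <- function(boxes, iou_threshold = 0.5) {
  if (nrow(boxes) <= 1) return(boxes)
  b <- boxes[order(-boxes$conf), ]
  iou <- box_iou(b, b)
  keep <- logical(nrow(b))
  alive <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[iou[i, ] > iou_threshold] <- FALSE
    alive[i] <- FALSE
  }
  b[keep, ]
}

#' Greedy matching of detections against ground truth
#'
#' Predictions are visited in descending confidence; each claims its
#' best-IoU unmatched ground truth if that IoU reaches the threshold (TP),
#' otherwise counts as FP. Unclaimed ground truths are FN.
#'
#' @param preds `pn_boxes` with confidences.
#' @param gts `pn_boxes` ground truth.
#' @param iou_threshold matching threshold (default 0.5).
#' @return list: counts tibble (tp, fp, fn) and `matches` — per-prediction
#'   tibble (pred, gt, iou, tp) in confidence order.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  ord <- order(-replace(preds$conf, is.na(preds$conf), 1))
  p <- preds[ord, ]
  np <- nrow(p); ngt <- nrow(gts)
  tp <- logical(np)
  match_gt <- rep(NA_integer_, np)
  match_iou <- rep(0, np)
  if (np > 0 && ngt > 0) {
    iou <- box_iou(p, gts)
    used <- logical(ngt)
    for (i in seq_len(np)) {
      cand <- which(!used & iou[i, ] >= iou_threshold)
      if (length(cand)) {
        j <- cand[which.max(iou[i, cand])]
        used[j] <- TRUE
        tp[i] <- TRUE
        match_gt[i] <- j
        match_iou[i] <- iou[i, j]
      }
    }
  }
  list(counts = tibble::tibble(tp = sum(tp), fp = np - sum(tp),
                               fn = ngt - sum(tp)),
       matches = tibble::tibble(pred = ord, gt = match_gt,
                                iou = match_iou, tp = tp))
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, F1 their harmonic mean;
#' 0/0 is defined as 0.
#'
#' @param counts tibble or named list with tp, fp, fn.
#' @return tibble (precision, recall, f1).
#' @export
#' @examples
#' precision_recall_f1(list(tp = 8, fp = 2, fn = 4))
precision_recall_f1 <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(precision = p, recall = r, f1 = f1)
}

#' Average precision at one IoU threshold
#'
#' Area under the precision-recall curve over the confidence sweep,
#' integrated with all-point interpolation (precision replaced by its
#' running maximum to the right); 11-point interpolation is available for
#' comparison.
#'
#' @param preds,gts `pn_boxes`; predictions carry confidences.
#' @param iou_threshold matching threshold.
#' @param interpolation "all_point" (default) or "11_point".
#' @return AP in `[0, 1]`, or NA when there is no ground truth.
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5,
                              interpolation = c("all_point", "11_point")) {
  interpolation <- match.arg(interpolation)
  if (nrow(gts) == 0) return(NA_real_)
  if (nrow(preds) == 0) return(0)
  m <- match_detections(preds, gts, iou_threshold)
  tp_cum <- cumsum(m$matches$tp)
  fp_cum <- cumsum(!m$matches$tp)
  recall <- tp_cum / nrow(gts)
  precision <- tp_cum / (tp_cum + fp_cum)
  if (interpolation == "11_point") {
    pr_at <- vapply(seq(0, 1, by = 0.1), function(r) {
      sel <- recall >= r
      if (any(sel)) max(precision[sel]) else 0
    }, numeric(1))
    return(mean(pr_at))
  }
  # monotone precision envelope, rectangle integration over recall
  rc <- c(0, recall)
  pr <- c(1, precision)
  pr <- rev(cummax(rev(pr)))
  sum(diff(rc) * pr[-1])
}

#' AP averaged over IoU thresholds 0.50 to 0.95
#'
#' Arithmetic mean of the average precision at the ten thresholds
#' 0.50, 0.55, ..., 0.95.
#'
#' @inheritParams average_precision
#' @return AP50:95 in `[0, 1]`.
#' @export
ap50_95 <- function(preds, gts) {
  ths <- seq(0.5, 0.95, by = 0.05)
  mean(vapply(ths, function(t) average_precision(preds, gts, t), numeric(1)))
}

#' Full metric set for one prediction/ground-truth pair
#'
#' @inheritParams average_precision
#' @param conf_threshold confidence cut used for the counting metrics
#'   (precision/recall/F1); AP uses the full sweep.
#' @return one-row tibble: precision, recall, f1, ap50, ap50_95, n_gt, n_pred.
#' @export
eval_metrics <- function(preds, gts, iou_threshold = 0.5,
                         conf_threshold = 0.25) {
  pc <- preds[!is.na(preds$conf) & preds$conf >= conf_threshold, ]
  m <- match_detections(pc, gts, iou_threshold)
  prf <- precision_recall_f1(m$counts)
  tibble::tibble(
    precision = prf$precision, recall = prf$recall, f1 = prf$f1,
    ap50 = average_precision(preds, gts, 0.5),
    ap50_95 = ap50_95(preds, gts),
    n_gt = nrow(gts), n_pred = nrow(pc))
}

#' Stratified evaluation over tagged ground truth
#'
#' Ground-truth boxes carry stratum tags (e.g. size class, illumination,
#' viewpoint); matched detections inherit the stratum of their ground truth,
#' unmatched detections are assigned by their own size class when the
#' stratum is `size`, otherwise by the image tag they came from. Boxes of
#' the omitted size class are excluded from both sides.
#'
#' @param preds `pn_boxes` with confidences and an `image` column.
#' @param gts `pn_boxes` with an `image` column and a column named by
#'   `stratum`.
#' @param stratum name of the tag column in `gts` ("size_class",
#'   "illumination", "viewpoint", ...).
#' @param image_size pixels, used to size-classify unmatched detections.
#' @param iou_threshold,conf_threshold evaluation thresholds.
#' @return tibble with one row per stratum plus an `overall` row, class
#'   `pn_eval`.
#' @export
stratified_eval <- function(preds, gts, stratum = "size_class",
                            image_size = 640, iou_threshold = 0.5,
                            conf_threshold = 0.25) {
  stopifnot(stratum %in% names(gts))
  if (!"image" %in% names(preds)) preds$image <- 1L
  if (!"image" %in% names(gts)) gts$image <- 1L
  if (stratum == "size_class") {
    gts <- gts[gts[[stratum]] != "omitted", ]
  }
  # per-image matching to carry strata onto detections
  pred_tag <- rep(NA_character_, nrow(preds))
  for (img in unique(c(preds$image, gts$image))) {
    pi <- which(preds$image == img)
    gix <- which(gts$image == img)
    if (!length(pi)) next
    m <- match_detections(preds[pi, ], gts[gix, ], iou_threshold)
    mm <- m$matches
    tag <- rep(NA_character_, length(pi))
    tag[mm$pred[mm$tp]] <- as.character(gts[[stratum]][gix[mm$gt[mm$tp]]])
    pred_tag[pi] <- tag
  }
  if (stratum == "size_class") {
    own <- as.character(size_class(preds, image_size))
    pred_tag[is.na(pred_tag)] <- own[is.na(pred_tag)]
  } else if (stratum %in% names(preds)) {
    pred_tag[is.na(pred_tag)] <- as.character(preds[[stratum]][is.na(pred_tag)])
  }
  levels_seen <- unique(as.character(gts[[stratum]]))
  rows <- lapply(levels_seen, function(lv) {
    g <- gts[as.character(gts[[stratum]]) == lv, ]
    p <- preds[!is.na(pred_tag) & pred_tag == lv, ]
    if (nrow(g) == 0) return(NULL)
    cbind(tibble::tibble(stratum = lv), eval_metrics(p, g, iou_threshold, conf_threshold))
  })
  overall <- cbind(tibble::tibble(stratum = "overall"),
                   eval_metrics(preds, gts, iou_threshold, conf_threshold))
  out <- dplyr::bind_rows(c(rows, list(overall)))
  class(out) <- c("pn_eval", class(out))
  out
}
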