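# Box-overlap geometry and the training loss. IoU and the EIoU border loss
# exist twice: as plain vectorized arithmetic (evaluation, tests) and as a
# tape expression (training), both derived from the same corner geometry.
#
# EIoU = 1 - IoU + rho^2(b, b_gt)/c^2 + rho^2(w, w_gt)/Cw^2 + rho^2(h, h_gt)/Ch^2
# with c the diagonal of the smallest enclosing box and Cw, Ch its sides.

.pn_eps <- 1e-7

boxes_to_corners <- function(b) {
  list(x1 = b$cx - b$w / 2, y1 = b$cy - b$h / 2,
       x2 = b$cx + b$w / 2, y2 = b$cy + b$h / 2)
}

#' Intersection over union of two box sets
#'
#' @param a,b `pn_boxes` tibbles (any consistent units). With
#'   `pairwise = FALSE` (default) returns the |a| x |b| IoU matrix;
#'   with `pairwise = TRUE`, a vector of row-wise IoUs (a and b must have
#'   equal row counts).
#' @return IoU values in `[0, 1]`; degenerate zero-area pairs give 0.
#' @export
#' @examples
#' a <- bbox_tibble(0, 0.25, 0.25, 0.5, 0.5)  # corners (0,0)-(2,2) on a 4-grid
#' b <- bbox_tibble(0, 0.5, 0.5, 0.5, 0.5)
#' box_iou(a, b)  # 1/7
box_iou <- function(a, b, pairwise = FALSE) {
  ca <- boxes_to_corners(a); cb <- boxes_to_corners(b)
  if (pairwise) {
    stopifnot(nrow(a) == nrow(b))
    iw <- pmax(0, pmin(ca$x2, cb$x2) - pmax(ca$x1, cb$x1))
    ih <- pmax(0, pmin(ca$y2, cb$y2) - pmax(ca$y1, cb$y1))
    inter <- iw * ih
    uni <- a$w * a$h + b$w * b$h - inter
    return(ifelse(uni <= 0, 0, inter / uni))
  }
  iw <- pmax(0, outer(ca$x2, cb$x2, pmin) - outer(ca$x1, cb$x1, pmax))
  ih <- pmax(0, outer(ca$y2, cb$y2, pmin) - outer(ca$y1, cb$y1, pmax))
  inter <- iw * ih
  uni <- outer(a$w * a$h, b$w * b$h, `+`) - inter
  out <- inter / uni
  out[uni <= 0] <- 0
  out
}

#' EIoU border regression loss
#'
#' `1 - IoU` plus three penalties normalized by the smallest enclosing box:
#' squared center distance over the squared enclosing diagonal, squared
#' width difference over the squared enclosing width, and squared height
#' difference over the squared enclosing height. Zero iff the boxes
#' coincide; invariant to joint translation and joint scaling.
#'
#' @param pred,gt `pn_boxes` tibbles with equal row counts (row-wise pairs).
#' @return numeric vector of losses, >= 0.
#' @export
#' @examples
#' p <- bbox_tibble(0, 0.25, 0.25, 0.5, 0.5)
#' g <- bbox_tibble(0, 0.5, 0.5, 0.5, 0.5)
#' eiou_loss(p, g)  # 6/7 + 2/18
eiou_loss <- function(pred, gt) {
  stopifnot(nrow(pred) == nrow(gt))
  if (nrow(pred) == 0) return(numeric())
  iou <- box_iou(pred, gt, pairwise = TRUE)
  cp <- boxes_to_corners(pred); cg <- boxes_to_corners(gt)
  ew <- pmax(cp$x2, cg$x2) - pmin(cp$x1, cg$x1)   # enclosing width
  eh <- pmax(cp$y2, cg$y2) - pmin(cp$y1, cg$y1)
  c2 <- ew^2 + eh^2
  rho2 <- (pred$cx - gt$cx)^2 + (pred$cy - gt$cy)^2
  out <- 1 - iou +
    rho2 / pmax(c2, .pn_eps) +
    (pred$w - gt$w)^2 / pmax(ew^2, .pn_eps) +
    (pred$h - gt$h)^2 / pmax(eh^2, .pn_eps)
  out[c2 < .pn_eps] <- 0    # both boxes degenerate at one point
  out
}

# Differentiable EIoU on tape vectors (grid units). px..gh are tg nodes or
# numerics; returns a tg vector node.
eiou_loss_tg <- function(px, py, pw, ph, gx, gy, gw, gh) {
  half <- function(v) tg_scale(v, 0.5)
  px1 <- tg_sub(px, half(pw)); px2 <- tg_add(px, half(pw))
  py1 <- tg_sub(py, half(ph)); py2 <- tg_add(py, half(ph))
  gx1 <- tg_sub(gx, half(gw)); gx2 <- tg_add(gx, half(gw))
  gy1 <- tg_sub(gy, half(gh)); gy2 <- tg_add(gy, half(gh))
  zero <- tg_const(rep(0, length(tg_value(px))))
  iw <- tg_pmax(zero, tg_sub(tg_pmin(px2, gx2), tg_pmax(px1, gx1)))
  ih <- tg_pmax(zero, tg_sub(tg_pmin(py2, gy2), tg_pmax(py1, gy1)))
  inter <- tg_mul(iw, ih)
  uni <- tg_sub(tg_add(tg_mul(pw, ph), tg_mul(gw, gh)), inter)
  iou <- tg_div(inter, tg_shift(uni, .pn_eps))
  ew <- tg_sub(tg_pmax(px2, gx2), tg_pmin(px1, gx1))
  eh <- tg_sub(tg_pmax(py2, gy2), tg_pmin(py1, gy1))
  c2 <- tg_add(tg_square(ew), tg_square(eh))
  rho2 <- tg_add(tg_square(tg_sub(px, gx)), tg_square(tg_sub(py, gy)))
  tg_add(tg_add(tg_shift(tg_neg(iou), 1),
                tg_div(rho2, tg_shift(c2, .pn_eps))),
         tg_add(tg_div(tg_square(tg_sub(pw, gw)), tg_shift(tg_square(ew), .pn_eps)),
                tg_div(tg_square(tg_sub(ph, gh)), tg_shift(tg_square(eh), .pn_eps))))
}

# ---- target assignment (stock multi-anchor rule) ---------------------------

#' Assign ground-truth boxes to anchors and grid cells
#'
#' Stock assignment: an anchor matches a target when the width and height
#' ratios both lie within a factor `anchor_t` (4.0); each match claims the
#' center cell plus up to two neighboring cells whose center offset is
#' within half a cell.
#'
#' @param targets `pn_boxes` tibble (normalized).
#' @param cfg `pn_config`.
#' @param input_size evaluation resolution in pixels.
#' @param anchor_t anchor ratio threshold.
#' @return list per scale: tibble (a, gi, gj, gx, gy, gw, gh) in grid units.
#' @keywords internal
build_targets <- function(targets, cfg, input_size = cfg$input_size,
                          anchor_t = 4.0) {
  strides <- c(8L, 16L, 32L)
  scale_f <- input_size / 640
  lapply(seq_along(strides), function(si) {
    s <- strides[si]
    ng <- input_size %/% s
    anch <- cfg$anchors[[si]] * scale_f / s          # grid units
    if (nrow(targets) == 0) {
      return(tibble::tibble(a = integer(), gi = integer(), gj = integer(),
                            gx = numeric(), gy = numeric(),
                            gw = numeric(), gh = numeric(), cid = integer()))
    }
    gx <- targets$cx * ng; gy <- targets$cy * ng
    gw <- targets$w * ng; gh <- targets$h * ng
    rows <- list(); k <- 0L
    for (a in seq_len(nrow(anch))) {
      rw <- gw / anch[a, 1]; rh <- gh / anch[a, 2]
      ok <- pmax(rw, 1 / rw) < anchor_t & pmax(rh, 1 / rh) < anchor_t
      for (ti in which(ok)) {
        ci <- floor(gx[ti]); cj <- floor(gy[ti])
        cells <- list(c(ci, cj))
        fx <- gx[ti] - ci; fy <- gy[ti] - cj
        if (fx < 0.5 && ci > 0) cells <- c(cells, list(c(ci - 1, cj)))
        if (fx >= 0.5 && ci < ng - 1) cells <- c(cells, list(c(ci + 1, cj)))
        if (fy < 0.5 && cj > 0) cells <- c(cells, list(c(ci, cj - 1)))
        if (fy >= 0.5 && cj < ng - 1) cells <- c(cells, list(c(ci, cj + 1)))
        for (cl in cells) {
          k <- k + 1L
          rows[[k]] <- c(a, cl[1], cl[2], gx[ti], gy[ti], gw[ti], gh[ti],
                         targets$class_id[ti])
        }
      }
    }
    if (!k) {
      return(tibble::tibble(a = integer(), gi = integer(), gj = integer(),
                            gx = numeric(), gy = numeric(),
                            gw = numeric(), gh = numeric(), cid = integer()))
    }
    m <- do.call(rbind, rows)
    out <- tibble::tibble(a = as.integer(m[, 1]), gi = as.integer(m[, 2]),
                          gj = as.integer(m[, 3]), gx = m[, 4], gy = m[, 5],
                          gw = m[, 6], gh = m[, 7], cid = as.integer(m[, 8]))
    # one assignment per (anchor, cell): keep the first
    dplyr::distinct(out, .data$a, .data$gi, .data$gj, .keep_all = TRUE)
  })
}

#' Composite detection training loss
#'
#' Weighted sum of the EIoU box component over assigned anchors, binary
#' cross-entropy on objectness over every anchor-cell (target = the detached
#' IoU of the decoded box for assigned entries, 0 elsewhere), and binary
#' cross-entropy on the class logits of assigned entries.
#'
#' @param raw list of three raw head outputs (tg nodes) from
#'   [forward_detector()].
#' @param targets `pn_boxes` tibble of ground truth (normalized).
#' @param cfg the `pn_config` used to build the model.
#' @param weights named numeric: box, obj, cls.
#' @param input_size pixels (defaults to the config).
#' @return tg scalar node with attribute `"components"` (named numeric:
#'   box, obj, cls, total).
#' @export
detection_loss <- function(raw, targets, cfg,
                           weights = c(box = 0.05, obj = 1.0, cls = 0.5),
                           input_size = cfg$input_size) {
  nc <- cfg$num_classes
  nf <- 5L + nc
  assigned <- build_targets(targets, cfg, input_size)
  balance <- c(4.0, 1.0, 0.4)
  strides <- c(8L, 16L, 32L)
  scale_f <- input_size / 640
  box_terms <- list(); cls_terms <- list(); obj_terms <- list()
  n_assigned <- 0L
  for (si in 1:3) {
    x <- raw[[si]]
    d <- dim(tg_value(x))
    ng_h <- d[2]; ng_w <- d[3]
    r <- tg_reshape(x, c(nf, 3L, ng_h, ng_w))
    tt <- assigned[[si]]
    obj_target <- array(0, c(3L, ng_h, ng_w))
    if (nrow(tt) > 0) {
      n_assigned <- n_assigned + nrow(tt)
      anch <- cfg$anchors[[si]] * scale_f / strides[si]
      # linear indices into (nf, 3, H, W): field k, anchor a, row gj+1, col gi+1
      lin <- function(k) {
        k + nf * (tt$a - 1L) + nf * 3L * tt$gj + nf * 3L * ng_h * tt$gi
      }
      txy_x <- tg_sigmoid(tg_gather(r, lin(1L)))
      txy_y <- tg_sigmoid(tg_gather(r, lin(2L)))
      twh_w <- tg_sigmoid(tg_gather(r, lin(3L)))
      twh_h <- tg_sigmoid(tg_gather(r, lin(4L)))
      px <- tg_add(tg_shift(tg_scale(txy_x, 2), -0.5), tg_const(tt$gi))
      py <- tg_add(tg_shift(tg_scale(txy_y, 2), -0.5), tg_const(tt$gj))
      pw <- tg_mul(tg_square(tg_scale(twh_w, 2)), tg_const(anch[tt$a, 1]))
      ph <- tg_mul(tg_square(tg_scale(twh_h, 2)), tg_const(anch[tt$a, 2]))
      el <- eiou_loss_tg(px, py, pw, ph,
                         tg_const(tt$gx), tg_const(tt$gy),
                         tg_const(tt$gw), tg_const(tt$gh))
      box_terms[[si]] <- tg_sum(el)
      # detached IoU as the objectness target
      iou_det <- box_iou(
        bbox_tibble(0, tg_value(px), tg_value(py), tg_value(pw), tg_value(ph)),
        bbox_tibble(0, tt$gx, tt$gy, tt$gw, tt$gh), pairwise = TRUE)
      obj_target[cbind(tt$a, tt$gj + 1L, tt$gi + 1L)] <- pmax(iou_det, 0)
      cls_logits <- tg_gather(r, as.vector(vapply(seq_len(nc), function(ci)
        lin(5L + ci), numeric(nrow(tt)))))
      # one-hot class targets laid out class-major to match the gather order
      ct <- rep(0, nrow(tt) * nc)
      ct[seq_len(nrow(tt)) + pmin(tt$cid, nc - 1L) * nrow(tt)] <- 1
      cls_terms[[si]] <- tg_scale(tg_bce_logits(cls_logits, ct), nrow(tt) * nc)
    }
    obj_idx <- which(array(TRUE, c(3L, ng_h, ng_w)))
    lin_obj <- 5L + nf * (rep(seq_len(3L), ng_h * ng_w) - 1L) +
      nf * 3L * (rep(rep(seq_len(ng_h), each = 3L), ng_w) - 1L) +
      nf * 3L * ng_h * (rep(seq_len(ng_w), each = 3L * ng_h) - 1L)
    obj_logits <- tg_gather(r, lin_obj)
    obj_terms[[si]] <- tg_scale(tg_bce_logits(obj_logits, as.vector(obj_target)),
                                balance[si])
  }
  box_l <- if (n_assigned > 0) {
    tg_scale(Reduce(tg_add, Filter(Negate(is.null), box_terms)), 1 / n_assigned)
  } else tg_const(0)
  cls_l <- if (length(Filter(Negate(is.null), cls_terms))) {
    tg_scale(Reduce(tg_add, Filter(Negate(is.null), cls_terms)),
             1 / max(n_assigned * nc, 1))
  } else tg_const(0)
  obj_l <- Reduce(tg_add, obj_terms)
  total <- tg_add(tg_add(tg_scale(box_l, weights[["box"]]),
                         tg_scale(obj_l, weights[["obj"]])),
                  tg_scale(cls_l, weights[["cls"]]))
  attr(total, "components") <- c(box = tg_value(box_l), obj = tg_value(obj_l),
                                 cls = tg_value(cls_l), total = tg_value(total))
  total
}
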