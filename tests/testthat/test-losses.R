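# Box geometry: IoU, the EIoU border loss and the composite training loss.

# corner helper: build a normalized box tibble from pixel corners on a
# unit-side canvas of the given size
from_corners <- function(x1, y1, x2, y2, side = 4) {
  bbox_tibble(0L, (x1 + x2) / 2 / side, (y1 + y2) / 2 / side,
              (x2 - x1) / side, (y2 - y1) / side)
}

test_that("iou matches hand geometry and is symmetric", {
  a <- from_corners(0, 0, 2, 2)
  b <- from_corners(1, 1, 3, 3)
  expect_equal(box_iou(a, a, pairwise = TRUE), 1)
  expect_equal(box_iou(a, b, pairwise = TRUE), 1 / 7, tolerance = 1e-12)
  expect_equal(box_iou(b, a, pairwise = TRUE), 1 / 7, tolerance = 1e-12)
  far <- from_corners(3, 3, 4, 4)
  expect_equal(box_iou(a, far, pairwise = TRUE), 0)
  degen <- bbox_tibble(0L, 0.5, 0.5, 0, 0)
  expect_equal(box_iou(degen, degen, pairwise = TRUE), 0)
})

test_that("eiou loss reproduces the closed-form example and its zero", {
  a <- from_corners(0, 0, 2, 2)
  b <- from_corners(1, 1, 3, 3)
  expect_equal(eiou_loss(a, a), 0)
  # areas 4/4, intersection 1, union 7; centers sqrt(2) apart; enclosure
  # 3x3 so c^2 = 18; equal sides kill the width/height terms:
  # 6/7 + 2/18 = 0.968254 (pixel units; scale-invariant, so the
  # normalized computation must agree)
  expect_equal(eiou_loss(a, b), 6 / 7 + 2 / 18, tolerance = 1e-12)
})

test_that("eiou is invariant to joint translation and scaling", {
  set.seed(10)
  for (i in 1:20) {
    p <- random_boxes(1, seed = i, conf = FALSE)
    g <- random_boxes(1, seed = i + 100, conf = FALSE)
    base <- eiou_loss(p, g)
    dx <- runif(1, -0.1, 0.1); dy <- runif(1, -0.1, 0.1); s <- runif(1, 0.5, 1.6)
    shift <- function(b) { b$cx <- b$cx + dx; b$cy <- b$cy + dy; b }
    scale <- function(b) { b$cx <- b$cx * s; b$cy <- b$cy * s
                           b$w <- b$w * s; b$h <- b$h * s; b }
    expect_equal(eiou_loss(shift(p), shift(g)), base, tolerance = 1e-10)
    expect_equal(eiou_loss(scale(p), scale(g)), base, tolerance = 1e-10)
  }
})

test_that("eiou dominates 1 - iou and decreases toward the target center", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_boxes(1, seed = 200 + i, conf = FALSE)
    g <- random_boxes(1, seed = 300 + i, conf = FALSE)
    expect_gte(eiou_loss(p, g) + 1e-12, 1 - box_iou(p, g, pairwise = TRUE))
  }
  # translate the prediction's center toward the target along a ray
  g <- bbox_tibble(0L, 0.6, 0.6, 0.2, 0.2)
  ts <- seq(0, 1, by = 0.1)
  losses <- vapply(ts, function(t) {
    p <- bbox_tibble(0L, 0.2 + t * 0.4, 0.2 + t * 0.4, 0.2, 0.2)
    eiou_loss(p, g)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("the tape-side eiou agrees with the numeric one and is differentiable", {
  ns <- asNamespace("pearnet")
  set.seed(12)
  p <- random_boxes(6, seed = 5, conf = FALSE)
  g <- random_boxes(6, seed = 6, conf = FALSE)
  node <- ns$eiou_loss_tg(ns$tg_const(p$cx), ns$tg_const(p$cy),
                          ns$tg_const(p$w), ns$tg_const(p$h),
                          ns$tg_const(g$cx), ns$tg_const(g$cy),
                          ns$tg_const(g$w), ns$tg_const(g$h))
  # the two implementations guard denominators differently (shift vs floor
  # by the 1e-7 epsilon), so agreement is to ~1e-6, not machine precision
  expect_equal(tgv(node), eiou_loss(p, g), tolerance = 1e-5)
  err <- grad_check(function(cx) {
    ns$tg_sum(ns$eiou_loss_tg(cx, ns$tg_const(p$cy), ns$tg_const(p$w),
                              ns$tg_const(p$h), ns$tg_const(g$cx),
                              ns$tg_const(g$cy), ns$tg_const(g$w),
                              ns$tg_const(g$h)))
  }, p$cx)
  expect_lt(err, 1e-5)
})

test_that("target assignment respects the anchor-ratio and neighbour rules", {
  ns <- asNamespace("pearnet")
  cfg <- model_config(variant = "baseline", input_size = 64)
  # a 0.5-wide box at center: matches large anchors only
  tt <- ns$build_targets(bbox_tibble(0L, 0.52, 0.52, 0.55, 0.55), cfg, 64)
  n_per_scale <- vapply(tt, nrow, integer(1))
  expect_true(n_per_scale[3] > 0)           # stride-32 anchors fit a 35-px box
  expect_true(all(tt[[3]]$gi >= 0 & tt[[3]]$gi < 2))
  # each match claims the center cell plus up to two neighbours
  expect_lte(max(n_per_scale), 3 * 3 * 3)
  empty <- ns$build_targets(bbox_tibble(), cfg, 64)
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
})

test_that("composite detection loss decomposes into its three components", {
  ns <- asNamespace("pearnet")
  det <- tiny_detector("baseline", 64L)
  set.seed(13)
  img <- array(runif(3 * 64 * 64), c(3, 64, 64))
  targets <- bbox_tibble(0L, 0.5, 0.5, 0.4, 0.4)
  raw <- forward_detector(det, img)
  w <- c(box = 0.05, obj = 1.0, cls = 0.5)
  loss <- detection_loss(raw, targets, det$cfg, w, 64)
  comp <- attr(loss, "components")
  expect_equal(comp[["total"]],
               w[["box"]] * comp[["box"]] + w[["obj"]] * comp[["obj"]] +
                 w[["cls"]] * comp[["cls"]],
               tolerance = 1e-12)
  expect_equal(tgv(loss), comp[["total"]])
  # independent reassembly of the box component from the decoded predictions
  assigned <- ns$build_targets(targets, det$cfg, 64)
  box_sum <- 0; n_as <- 0
  for (si in 1:3) {
    tt <- assigned[[si]]
    if (!nrow(tt)) next
    x <- tgv(raw[[si]])
    nf <- 6L
    d <- dim(x)
    dim(x) <- c(nf, 3L, d[2], d[3])
    anch <- det$cfg$anchors[[si]] * (64 / 640) / c(8, 16, 32)[si]
    for (r in seq_len(nrow(tt))) {
      v <- x[, tt$a[r], tt$gj[r] + 1L, tt$gi[r] + 1L]
      sg <- function(z) 1 / (1 + exp(-z))
      px <- 2 * sg(v[1]) - 0.5 + tt$gi[r]
      py <- 2 * sg(v[2]) - 0.5 + tt$gj[r]
      pw <- (2 * sg(v[3]))^2 * anch[tt$a[r], 1]
      ph <- (2 * sg(v[4]))^2 * anch[tt$a[r], 2]
      box_sum <- box_sum + eiou_loss(bbox_tibble(0L, px, py, pw, ph),
                                     bbox_tibble(0L, tt$gx[r], tt$gy[r],
                                                 tt$gw[r], tt$gh[r]))
      n_as <- n_as + 1
    }
  }
  expect_gt(n_as, 0)
  expect_equal(comp[["box"]], box_sum / n_as, tolerance = 1e-6)
})

test_that("an empty image trains objectness toward background only", {
  det <- tiny_detector("baseline", 64L)
  set.seed(14)
  img <- array(runif(3 * 64 * 64), c(3, 64, 64))
  raw <- forward_detector(det, img)
  loss <- detection_loss(raw, bbox_tibble(), det$cfg, input_size = 64)
  comp <- attr(loss, "components")
  expect_equal(comp[["box"]], 0)
  expect_equal(comp[["cls"]], 0)
  expect_gt(comp[["obj"]], 0)
  # saturated-negative objectness drives the component toward zero
  raw_neg <- lapply(raw, function(r) {
    v <- tgv(r)
    nf <- 6L
    dim(v) <- c(nf, length(v) / nf)
    v[5, ] <- -30
    dim(v) <- dim(tgv(r))
    pearnet:::tg_const(v)
  })
  comp_neg <- attr(detection_loss(raw_neg, bbox_tibble(), det$cfg,
                                  input_size = 64), "components")
  expect_lt(comp_neg[["obj"]], 1e-8)
})
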