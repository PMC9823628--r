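# Detection metrics against brute-force oracles.

test_that("greedy NMS keeps the confident box among heavy overlaps", {
  b <- bbox_tibble(0L, c(0.5, 0.52), c(0.5, 0.5), c(0.3, 0.3), c(0.3, 0.3),
                   conf = c(0.9, 0.8))
  expect_gt(box_iou(b[1, ], b[2, ], pairwise = TRUE), 0.5)
  kept <- nms_boxes(b, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$conf, 0.9)
  # disjoint boxes survive
  d <- bbox_tibble(0L, c(0.2, 0.8), c(0.2, 0.8), c(0.2, 0.2), c(0.2, 0.2),
                   conf = c(0.9, 0.8))
  expect_equal(nrow(nms_boxes(d, 0.5)), 2)
  one <- bbox_tibble(0L, 0.5, 0.5, 0.2, 0.2, conf = 0.7)
  expect_identical(nms_boxes(one, 0.5), one)
})

test_that("raw-head decoding respects the confidence threshold", {
  det <- tiny_detector("baseline", 64L)
  set.seed(15)
  raw <- forward_detector(det, array(runif(3 * 64 * 64), c(3, 64, 64)))
  # saturate everything far below threshold
  raw_low <- lapply(raw, function(r) {
    v <- tgv(r)
    dim6 <- c(6L, length(v) / 6L)
    dim(v) <- dim6
    v[5, ] <- -20
    dim(v) <- dim(tgv(r))
    pearnet:::tg_const(v)
  })
  expect_equal(nrow(decode_and_nms(raw_low, det$cfg, 0.25, 0.5, 64)), 0)
  # one confident cell decodes to one box at the right place
  raw_one <- lapply(seq_along(raw), function(si) {
    v <- tgv(raw[[si]])
    d <- dim(v)
    dim(v) <- c(6L, 3L, d[2], d[3])
    v[5, , , ] <- -20
    if (si == 1) {
      v[5, 1, 4, 4] <- 20   # objectness ~1 at cell (3, 3) zero-based
      v[6, 1, 4, 4] <- 20
      v[1:2, 1, 4, 4] <- 0  # centered offsets
    }
    dim(v) <- d
    pearnet:::tg_const(v)
  })
  out <- decode_and_nms(raw_one, det$cfg, 0.25, 0.5, 64)
  expect_equal(nrow(out), 1)
  expect_equal(out$cx, (0.5 + 3) * 8 / 64, tolerance = 1e-9)
  expect_equal(out$cy, (0.5 + 3) * 8 / 64, tolerance = 1e-9)
})

test_that("matching equals the greedy oracle on random layouts up to 6 boxes", {
  for (s in 1:30) {
    set.seed(s)
    np <- sample(0:6, 1); ng <- sample(0:6, 1)
    preds <- random_boxes(np, seed = 1000 + s)
    gts <- random_boxes(ng, seed = 2000 + s, conf = FALSE)
    m <- match_detections(preds, gts, 0.5)
    o <- greedy_match_oracle(preds, gts, 0.5)
    expect_equal(m$counts$tp, o$tp)
    expect_equal(m$counts$fp, o$fp)
    expect_equal(m$counts$fn, o$fn)
    expect_equal(m$counts$tp + m$counts$fn, ng)
  }
})

test_that("precision/recall/F1 follow their closed forms", {
  out <- precision_recall_f1(list(tp = 8, fp = 2, fn = 4))
  expect_equal(out$precision, 0.8)
  expect_equal(out$recall, 2 / 3, tolerance = 1e-9)
  expect_equal(out$f1, 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3), tolerance = 1e-9)
  expect_equal(round(out$f1, 4), 0.7273)
  expect_equal(precision_recall_f1(list(tp = 3, fp = 1, fn = 1))$f1, 0.75)
  expect_equal(precision_recall_f1(list(tp = 0, fp = 0, fn = 0))$f1, 0)
  # P == R == x gives F1 == x
  out2 <- precision_recall_f1(list(tp = 6, fp = 2, fn = 2))
  expect_equal(out2$precision, out2$recall)
  expect_equal(out2$f1, out2$precision)
})

test_that("average precision integrates the PR curve like the oracle", {
  gts <- random_boxes(4, seed = 50, conf = FALSE)
  perfect <- gts
  perfect$conf <- seq(0.9, 0.6, length.out = 4)
  expect_equal(average_precision(perfect, gts, 0.5), 1)
  wrong <- random_boxes(4, seed = 51)
  wrong$cx <- wrong$cx * 0 + 0.01
  wrong$w <- wrong$w * 0 + 0.01
  expect_equal(average_precision(wrong, gts, 0.5), 0)
  # the worked 5-prediction layout: correct at ranks 1, 2, 4
  g <- bbox_tibble(0L, c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8),
                   rep(0.1, 3), rep(0.1, 3))
  p <- bbox_tibble(0L, c(0.2, 0.5, 0.05, 0.8, 0.95),
                   c(0.2, 0.5, 0.95, 0.8, 0.05),
                   rep(0.1, 5), rep(0.1, 5),
                   conf = c(0.9, 0.8, 0.7, 0.6, 0.5))
  expect_equal(average_precision(p, g, 0.5), ap_oracle(p, g, 0.5),
               tolerance = 1e-12)
  expect_equal(average_precision(p, g, 0.5), (1 / 3) * 1 + (1 / 3) * 1 + (1 / 3) * 0.75,
               tolerance = 1e-12)
  # random layouts against the oracle
  for (s in 1:15) {
    preds <- random_boxes(8, seed = 3000 + s)
    gg <- random_boxes(5, seed = 4000 + s, conf = FALSE)
    expect_equal(average_precision(preds, gg, 0.5), ap_oracle(preds, gg, 0.5),
                 tolerance = 1e-12)
  }
})

test_that("AP is invariant to monotone confidence rescaling and non-increasing in IoU", {
  preds <- random_boxes(10, seed = 60)
  gts <- random_boxes(6, seed = 61, conf = FALSE)
  base <- average_precision(preds, gts, 0.5)
  resc <- preds
  resc$conf <- stats::plogis(3 * preds$conf - 1)   # strictly monotone map
  expect_equal(average_precision(resc, gts, 0.5), base, tolerance = 1e-12)
  ths <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(ths, function(t) average_precision(preds, gts, t), numeric(1))
  expect_true(all(diff(aps) <= 1e-12))
  expect_equal(ap50_95(preds, gts), mean(aps), tolerance = 1e-12)
  expect_lte(ap50_95(preds, gts), average_precision(preds, gts, 0.5) + 1e-12)
})

test_that("ap50_95 edge cases: constant AP and perfect detections", {
  gts <- random_boxes(3, seed = 70, conf = FALSE)
  perfect <- gts
  perfect$conf <- c(0.9, 0.8, 0.7)
  expect_equal(ap50_95(perfect, gts), 1)
  expect_true(is.na(average_precision(perfect, bbox_tibble())))
})

test_that("stratified evaluation is additive and collapses for one stratum", {
  # two disjoint strata on one image
  g_small <- bbox_tibble(0L, c(0.1, 0.3), c(0.1, 0.3), 0.025, 0.025)
  g_large <- bbox_tibble(0L, c(0.7, 0.9), c(0.7, 0.9), 0.12, 0.12)
  gts <- dplyr::bind_rows(g_small, g_large)
  gts$image <- 1L
  gts$size_class <- as.character(size_class(gts, 640))
  expect_setequal(unique(gts$size_class), c("small", "large"))
  # a perfect detector for the small stratum, silence elsewhere
  preds <- g_small
  preds$conf <- c(0.9, 0.8)
  preds$image <- 1L
  ev <- stratified_eval(preds, gts, "size_class", image_size = 640)
  expect_equal(ev$ap50[ev$stratum == "small"], 1)
  expect_equal(ev$ap50[ev$stratum == "large"], 0)
  expect_equal(sum(ev$n_gt[ev$stratum != "overall"]),
               ev$n_gt[ev$stratum == "overall"])
  # single-stratum input: stratified equals overall
  ev2 <- stratified_eval(preds, gts[gts$size_class == "small", ],
                         "size_class", image_size = 640)
  expect_equal(ev2$ap50[ev2$stratum == "small"],
               ev2$ap50[ev2$stratum == "overall"])
  # omitted boxes are excluded from both sides
  gts3 <- dplyr::bind_rows(gts, {
    tmp <- bbox_tibble(0L, 0.5, 0.5, 0.012, 0.012)
    tmp$image <- 1L
    tmp$size_class <- "omitted"
    tmp
  })
  ev3 <- stratified_eval(preds, gts3, "size_class", image_size = 640)
  expect_equal(ev3$n_gt[ev3$stratum == "overall"], 4)
})
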