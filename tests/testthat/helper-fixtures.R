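# Shared helpers: finite-difference gradients, brute-force metric oracles,
# and cached small fixtures built in code.

tgv <- function(x) pearnet:::tg_value(x)

num_grad <- function(fn, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  if (is.null(dim(x))) g <- as.vector(g)
  g
}

# relative max error between analytic and numeric gradient of fn_tg at x
grad_check <- function(fn_tg, x) {
  p <- pearnet:::tg_param(x)
  pearnet:::tg_backward(fn_tg(p))
  ng <- num_grad(function(xx) tgv(fn_tg(pearnet:::tg_param(xx))), x)
  max(abs(p$grad - ng)) / max(1, max(abs(ng)))
}

# exhaustive-assignment oracle for TP counting: maximize the number of
# one-to-one (pred, gt) pairs with IoU >= threshold, visiting predictions in
# confidence order greedily as the implementation defines
greedy_match_oracle <- function(preds, gts, thr) {
  ord <- order(-preds$conf)
  used <- logical(nrow(gts))
  tp <- 0L
  iou <- if (nrow(preds) && nrow(gts)) box_iou(preds[ord, ], gts) else
    matrix(0, nrow(preds), nrow(gts))
  for (i in seq_len(nrow(preds))) {
    cand <- which(!used & iou[i, ] >= thr)
    if (length(cand)) {
      j <- cand[which.max(iou[i, cand])]
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nrow(preds) - tp, fn = nrow(gts) - tp)
}

# independent PR-curve integrator: explicit rectangle sum over the
# monotone precision envelope
ap_oracle <- function(preds, gts, thr) {
  if (nrow(gts) == 0) return(NA_real_)
  if (nrow(preds) == 0) return(0)
  m <- match_detections(preds, gts, thr)
  tp <- m$matches$tp
  rec <- cumsum(tp) / nrow(gts)
  prec <- cumsum(tp) / seq_along(tp)
  ap <- 0
  prev_r <- 0
  for (i in seq_along(tp)) {
    env <- max(prec[i:length(tp)])
    ap <- ap + (rec[i] - prev_r) * env
    prev_r <- rec[i]
  }
  ap
}

random_boxes <- function(n, seed, conf = TRUE) {
  set.seed(seed)
  w <- runif(n, 0.05, 0.3); h <- runif(n, 0.05, 0.3)
  bbox_tibble(0L, runif(n, 0.2, 0.8), runif(n, 0.2, 0.8), w, h,
              conf = if (conf) runif(n) else NULL)
}

# a small detector, built once per variant and memoized across tests
.det_cache <- new.env(parent = emptyenv())
tiny_detector <- function(variant = "FP", input_size = 64L,
                          width_multiple = 0.25) {
  key <- paste(variant, input_size, width_multiple, sep = "_")
  if (is.null(.det_cache[[key]])) {
    set.seed(7)
    .det_cache[[key]] <- build_model(model_config(
      variant = variant, input_size = input_size,
      width_multiple = width_multiple))
  }
  .det_cache[[key]]
}

easy_scene_set <- function(n = 4, image_size = 96, seed_base = 100) {
  lapply(seq_len(n), function(i) {
    sc <- render_scene(scene_spec(image_size = image_size, n_pears = 2,
                                  radius_mix = c(0, 0, 1),
                                  occlusion_fraction = 0,
                                  seed = seed_base + i))
    list(image = sc$image, boxes = sc$boxes, stem = sprintf("s%02d", i))
  })
}
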