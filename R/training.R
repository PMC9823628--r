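# Stochastic-gradient training of any detector variant: SGD with momentum
# and weight decay, cosine learning-rate annealing with a short linear
# warmup, gradient accumulation over the batch, per-epoch train/validation
# loss curves, and best-validation weight retention.

#' Training configuration
#'
#' Defaults follow the standard recipe for this detector family: batch of 8 images, 200 epochs,
#' initial learning rate 0.01, weight decay 0.00048, momentum 0.937,
#' 640 px inputs. The learning rate is cosine-annealed to `lr0 * lrf`.
#'
#' @param batch_size images per optimizer step.
#' @param epochs training epochs (>= 1).
#' @param lr0 initial learning rate.
#' @param lrf final learning-rate factor of the cosine schedule.
#' @param weight_decay L2 penalty applied to convolution/linear weights
#'   (not to biases or normalization parameters).
#' @param momentum SGD momentum factor.
#' @param input_size training resolution in pixels (multiple of 32).
#' @param seed integer seed for shuffling, augmentation and dropout.
#' @param augment logical; apply the random augmentation stack when reading
#'   training images.
#' @param warmup_iters linear warmup iterations.
#' @param loss_weights named numeric (box, obj, cls).
#' @param pretrained_weights optional path to a weights RDS loaded before
#'   training (transfer-learning hook).
#' @return a `pn_train_config`.
#' @export
train_config <- function(batch_size = 8L, epochs = 200L, lr0 = 0.01,
                         lrf = 0.1, weight_decay = 0.00048,
                         momentum = 0.937, input_size = 640L, seed = 0L,
                         augment = FALSE, warmup_iters = 50L,
                         loss_weights = c(box = 0.05, obj = 1.0, cls = 0.5),
                         pretrained_weights = NULL) {
  stopifnot(batch_size >= 1, epochs >= 1, lr0 > 0, weight_decay >= 0,
            momentum >= 0, momentum < 1, input_size %% 32 == 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0, lrf = lrf,
                 weight_decay = weight_decay, momentum = momentum,
                 input_size = as.integer(input_size), seed = as.integer(seed),
                 augment = isTRUE(augment), warmup_iters = as.integer(warmup_iters),
                 loss_weights = loss_weights,
                 pretrained_weights = pretrained_weights),
            class = "pn_train_config")
}

#' Read images and labels of one split into memory
#'
#' @param dir fixture-dataset directory ([make_fixture_set()] layout).
#' @param split "train", "val" or "test".
#' @return list of `list(image, boxes, stem)`.
#' @export
load_samples <- function(dir, split = "train") {
  idx <- load_dataset_index(dir, split)
  lapply(seq_len(nrow(idx)), function(i) {
    list(image = png::readPNG(idx$image_path[i]),
         boxes = if (file.exists(idx$label_path[i])) {
           suppressWarnings(read_annotations(idx$label_path[i]))
         } else bbox_tibble(),
         stem = idx$stem[i])
  })
}

cosine_lr <- function(epoch, epochs, lr0, lrf) {
  lr0 * ((1 - lrf) * 0.5 * (1 + cos(pi * (epoch - 1) / max(epochs - 1, 1))) + lrf)
}

#' Train a detector
#'
#' @param det a `pn_detector` (modified in place by reference semantics of
#'   its parameter nodes; also returned).
#' @param dataset either a fixture-dataset directory or a list with `train`
#'   and optionally `val` elements, each a list of `list(image, boxes)`.
#' @param cfg a `pn_train_config`.
#' @param verbose print per-epoch losses.
#' @return a `pn_fit`: list(detector, history tibble, best_epoch,
#'   best_weights).
#' @export
train <- function(det, dataset, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(det, "pn_detector"), inherits(cfg, "pn_train_config"))
  if (is.character(dataset)) {
    dataset <- list(train = load_samples(dataset, "train"),
                    val = tryCatch(load_samples(dataset, "val"),
                                   error = function(e) list()))
    if (!length(dataset$val)) dataset$val <- NULL
  }
  train_set <- dataset$train
  if (!length(train_set)) stop("empty training split")
  val_set <- dataset$val
  if (!is.null(cfg$pretrained_weights)) {
    det <- load_pretrained(det, cfg$pretrained_weights)
  }
  params <- detector_params(det)
  is_weight <- vapply(params, function(p) !is.null(dim(tg_value(p))), logical(1))
  vel <- lapply(params, function(p) { v <- tg_value(p); v[] <- 0; v })
  history <- list()
  best <- list(val = Inf, epoch = NA_integer_, weights = NULL)
  it <- 0L
  set.seed(cfg$seed)
  mcfg <- det$cfg
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(seq_along(train_set))
    lr_e <- cosine_lr(epoch, cfg$epochs, cfg$lr0, cfg$lrf)
    ep_losses <- c(total = 0, box = 0, obj = 0, cls = 0)
    nb <- 0L
    batch_starts <- seq(1, length(ord), by = cfg$batch_size)
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + cfg$batch_size - 1L, length(ord))]
      tg_zero_grad(params)
      bloss <- c(total = 0, box = 0, obj = 0, cls = 0)
      for (i in idx) {
        smp <- train_set[[i]]
        img <- smp$image; bx <- smp$boxes
        if (cfg$augment) {
          aug <- augment(img, bx, seed = stats::runif(1, 0, 2^30))
          img <- aug$image; bx <- aug$boxes
        }
        raw <- forward_detector(det, img, training = TRUE)
        loss <- detection_loss(raw, bx, mcfg, cfg$loss_weights, cfg$input_size)
        lv <- attr(loss, "components")
        if (!is.finite(lv[["total"]])) {
          stop(sprintf("training diverged at epoch %d (loss=%g); try a lower lr0",
                       epoch, lv[["total"]]))
        }
        tg_backward(loss)
        bloss <- bloss + lv[c("total", "box", "obj", "cls")]
      }
      it <- it + 1L
      warm <- if (it <= cfg$warmup_iters) it / cfg$warmup_iters else 1
      lr <- lr_e * warm
      nim <- length(idx)
      for (k in seq_along(params)) {
        p <- params[[k]]
        g <- p$grad
        if (is.null(g)) next
        g <- g / nim
        if (cfg$weight_decay > 0 && is_weight[k]) g <- g + cfg$weight_decay * p$value
        vel[[k]] <- cfg$momentum * vel[[k]] + g
        p$value <- p$value - lr * vel[[k]]
      }
      ep_losses <- ep_losses + bloss / nim
      nb <- nb + 1L
    }
    ep_losses <- ep_losses / nb
    val_losses <- c(total = NA_real_, box = NA_real_)
    if (!is.null(val_set) && length(val_set)) {
      vt <- c(total = 0, box = 0)
      for (smp in val_set) {
        raw <- forward_detector(det, smp$image, training = FALSE)
        lv <- attr(detection_loss(raw, smp$boxes, mcfg, cfg$loss_weights,
                                  cfg$input_size), "components")
        vt <- vt + lv[c("total", "box")]
      }
      val_losses <- vt / length(val_set)
      if (val_losses[["total"]] < best$val) {
        best$val <- val_losses[["total"]]
        best$epoch <- epoch
        best$weights <- detector_weights(det)
      }
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr_e,
      train_total = ep_losses[["total"]], train_box = ep_losses[["box"]],
      train_obj = ep_losses[["obj"]], train_cls = ep_losses[["cls"]],
      val_total = val_losses[["total"]], val_box = val_losses[["box"]])
    if (verbose) {
      message(sprintf("epoch %3d  lr %.4f  train %.4f  val %s", epoch, lr_e,
                      ep_losses[["total"]],
                      ifelse(is.na(val_losses[["total"]]), "-",
                             sprintf("%.4f", val_losses[["total"]]))))
    }
  }
  fit <- structure(list(detector = det,
                        history = dplyr::bind_rows(history),
                        best_epoch = best$epoch,
                        best_weights = best$weights,
                        train_cfg = cfg),
                   class = "pn_fit")
  fit
}

#' Run a detector on one image
#'
#' @param det a `pn_detector`.
#' @param image H x W x 3 array (or 3 x H x W tensor).
#' @param conf_threshold,iou_threshold post-processing thresholds.
#' @return `pn_boxes` with confidences.
#' @export
detect_image <- function(det, image, conf_threshold = 0.25,
                         iou_threshold = 0.5) {
  raw <- forward_detector(det, image, training = FALSE)
  sz <- if (length(dim(image)) == 3 && dim(image)[3] == 3) dim(image)[1] else dim(image)[2]
  decode_and_nms(raw, det$cfg, conf_threshold, iou_threshold, input_size = sz)
}

#' Evaluate a detector over a sample list or fixture dataset
#'
#' @param det a `pn_detector`.
#' @param dataset directory or list of `list(image, boxes, stem)` samples.
#' @param split split to evaluate when `dataset` is a directory.
#' @param stratum stratification tag ("size_class", "illumination",
#'   "viewpoint", or NULL for overall only).
#' @param conf_threshold,iou_threshold evaluation thresholds.
#' @return `pn_eval` tibble from [stratified_eval()].
#' @export
evaluate_detector <- function(det, dataset, split = "test",
                              stratum = "size_class",
                              conf_threshold = 0.25, iou_threshold = 0.5) {
  if (is.character(dataset)) {
    dataset <- load_samples(dataset, split)
  }
  sz <- dim(dataset[[1]]$image)[1]
  preds <- list(); gts <- list()
  for (i in seq_along(dataset)) {
    smp <- dataset[[i]]
    p <- detect_image(det, smp$image, conf_threshold = 0.001,
                      iou_threshold = iou_threshold)
    if (nrow(p)) { p$image <- i; preds[[length(preds) + 1L]] <- p }
    g <- smp$boxes
    if (nrow(g)) {
      g$image <- i
      g$size_class <- as.character(size_class(g, sz))
      gts[[length(gts) + 1L]] <- g
    }
  }
  preds <- if (length(preds)) dplyr::bind_rows(preds) else
    cbind(bbox_tibble(), tibble::tibble(image = integer()))
  gts <- if (length(gts)) dplyr::bind_rows(gts) else
    cbind(bbox_tibble(), tibble::tibble(image = integer(),
                                        size_class = character()))
  if (is.null(stratum)) stratum <- "size_class"
  stratified_eval(preds, gts, stratum = stratum, image_size = sz,
                  iou_threshold = iou_threshold,
                  conf_threshold = conf_threshold)
}

#' Save a training checkpoint
#'
#' @param det a `pn_detector` (or the detector inside a `pn_fit`).
#' @param path RDS output path.
#' @param epoch optional epoch tag.
#' @export
save_checkpoint <- function(det, path, epoch = NA_integer_) {
  if (inherits(det, "pn_fit")) det <- det$detector
  saveRDS(list(cfg = det$cfg, weights = detector_weights(det), epoch = epoch),
          path)
  invisible(path)
}

#' Load a training checkpoint into a freshly built detector
#'
#' @param path RDS checkpoint path.
#' @return a `pn_detector`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  det <- build_model(ck$cfg)
  load_pretrained(det, ck$weights)
}
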