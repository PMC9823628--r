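# Detector assembly: CSPDarknet backbone, path-aggregation neck with the
# collaboration-perception modifications (cross-scale skip connections,
# transformer encoder in the low-resolution path P3, fusion CSP in the
# medium-resolution path P2), and the three-scale anchor-based head.

# Stock anchor priors (pixels at a 640 input), three per head scale.
pn_default_anchors <- function() {
  list(
    p8  = matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
    p16 = matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
    p32 = matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE))
}

#' Model configuration
#'
#' Collects the depth/width multiples of the small sub-version, the anchor
#' set, transformer-encoder settings, and the ablation variant selecting the
#' neck wiring.
#'
#' @param variant one of `"baseline"` (stock PANet), `"SC"` (adds the two
#'   cross-scale skip connections), `"TE"` (SC plus a transformer encoder
#'   replacing the CSP2 of the low-resolution path P3), `"TC"` (SC plus the
#'   fusion CSP replacing the CSP2 of the medium-resolution path P2), or
#'   `"FP"` (all of the above).
#' @param depth_multiple,width_multiple scaling ratios of block repeats and
#'   channel widths (0.33 / 0.50 for the small sub-version).
#' @param num_classes number of object classes (1 for the pear task).
#' @param input_size square input resolution in pixels (even, default 640).
#' @param te_heads,te_dropout attention heads and dropout of the transformer
#'   encoder blocks.
#' @param anchors list of three (n x 2) matrices of anchor (width, height)
#'   pixels at a 640 input, one per head stride (8, 16, 32); rescaled
#'   automatically for other input sizes.
#' @return a `pn_config` list.
#' @export
#' @examples
#' cfg <- model_config(variant = "baseline", input_size = 64)
model_config <- function(variant = c("FP", "baseline", "SC", "TE", "TC"),
                         depth_multiple = 0.33, width_multiple = 0.50,
                         num_classes = 1L, input_size = 640L,
                         te_heads = 4L, te_dropout = 0.1,
                         anchors = pn_default_anchors()) {
  variant <- match.arg(variant)
  stopifnot(depth_multiple > 0, width_multiple > 0, num_classes >= 1,
            input_size %% 32 == 0, te_heads >= 1,
            te_dropout >= 0, te_dropout < 1, length(anchors) == 3)
  structure(list(variant = variant,
                 depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 te_heads = as.integer(te_heads),
                 te_dropout = te_dropout,
                 anchors = anchors),
            class = "pn_config")
}

#' Read a model configuration from a YAML file
#' @param path YAML file with any subset of the `model_config()` arguments.
#' @return a `pn_config`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$anchors)) {
    y$anchors <- lapply(y$anchors, function(a) matrix(unlist(a), ncol = 2, byrow = TRUE))
  }
  do.call(model_config, y)
}

scaled_width <- function(c, wm) {
  # round channel widths to multiples of 8, never below 8
  max(8L, as.integer(round(c * wm / 8) * 8))
}

scaled_depth <- function(n, dm) max(1L, as.integer(round(n * dm)))

#' Build a detector
#'
#' Assembles backbone, neck and head for the configured ablation variant and
#' initializes all weights from the current RNG state (seed it for
#' reproducible builds). The returned object records a wiring graph
#' (`$graph`) used for structural inspection.
#'
#' @param cfg a `pn_config` from [model_config()].
#' @return a `pn_detector`.
#' @export
#' @examples
#' set.seed(1)
#' det <- build_model(model_config(variant = "baseline", input_size = 64))
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "pn_config"))
  wm <- cfg$width_multiple; dm <- cfg$depth_multiple
  w <- function(c) scaled_width(c, wm)
  d <- function(n) scaled_depth(n, dm)
  nc <- cfg$num_classes
  no <- 3L * (5L + nc)
  use_skips <- cfg$variant %in% c("SC", "TE", "TC", "FP")
  use_te <- cfg$variant %in% c("TE", "FP")
  use_tc <- cfg$variant %in% c("TC", "FP")

  mods <- list(
    focus = focus_block(3L, w(64)),
    b1 = cbs_block(w(64), w(128), 3L, 2L),
    b2 = csp_block(w(128), w(128), d(3), "CSP1"),
    b3 = cbs_block(w(128), w(256), 3L, 2L),
    b4 = csp_block(w(256), w(256), d(9), "CSP1"),
    b5 = cbs_block(w(256), w(512), 3L, 2L),
    b6 = csp_block(w(512), w(512), d(9), "CSP1"),
    b7 = cbs_block(w(512), w(1024), 3L, 2L),
    spp = spp_block(w(1024), w(1024)),
    b9 = csp_block(w(1024), w(1024), d(3), "CSP2"),
    n10 = cbs_block(w(1024), w(512), 1L),
    n13 = csp_block(2L * w(512), w(512), d(3), "CSP2"),
    n14 = cbs_block(w(512), w(256), 1L),
    p1_csp = csp_block(2L * w(256), w(256), d(3), "CSP2"),
    down18 = cbs_block(w(256), w(256), 3L, 2L),
    down21 = cbs_block(w(512), w(512), 3L, 2L),
    head_p8 = conv_bias_block(w(256), no, 1L),
    head_p16 = conv_bias_block(w(512), no, 1L),
    head_p32 = conv_bias_block(w(1024), no, 1L))

  mods$p2_csp <- if (use_tc) {
    csp_ff(2L * w(256), w(512), cfg$te_heads, cfg$te_dropout)
  } else {
    csp_block(2L * w(256), w(512), d(3), "CSP2")
  }
  mods$p3_csp <- if (use_te) {
    transformer_encoder(2L * w(512), cfg$te_heads, cfg$te_dropout)
  } else {
    csp_block(2L * w(512), w(1024), d(3), "CSP2")
  }
  # transformer encoder is shape-preserving (2*w512 in/out); a stock CSP2
  # maps 2*w512 -> w1024, the same width, so head_p32 input width matches
  if (use_skips) {
    mods$skip_p2 <- cbs_block(2L * w(256), w(256), 1L, 2L)
    mods$skip_p3a <- cbs_block(2L * w(256), w(512), 1L, 2L)
    mods$skip_p3b <- cbs_block(w(512), w(512), 1L, 2L)
  }

  graph <- build_graph(cfg)
  # objectness prior: start detection heads expecting ~8 objects per image
  for (hname in c("head_p8", "head_p16", "head_p32")) {
    stride <- c(head_p8 = 8, head_p16 = 16, head_p32 = 32)[[hname]]
    b <- tg_value(mods[[hname]]$params$b)
    ncell <- (cfg$input_size / stride)^2
    obj_idx <- seq(5L, by = 5L + nc, length.out = 3L)
    b[obj_idx] <- log(8 / ncell / (1 - min(8 / ncell, 0.99)))
    cls_idx <- setdiff(seq_along(b), c(obj_idx, outer(1:4, (0:2) * (5L + nc), `+`)))
    b[cls_idx] <- log(0.6 / max(nc - 0.99, 0.01))
    mods[[hname]]$params$b$value <- b
  }
  structure(list(cfg = cfg, mods = mods, graph = graph),
            class = "pn_detector")
}

# Wiring table: one row per neck/backbone connection, used by tests that
# inspect how many feature-extraction modules each skip connection bypasses.
build_graph <- function(cfg) {
  edges <- list(
    c("input", "focus"), c("focus", "b1"), c("b1", "b2"), c("b2", "b3"),
    c("b3", "b4"), c("b4", "b5"), c("b5", "b6"), c("b6", "b7"),
    c("b7", "spp"), c("spp", "b9"), c("b9", "n10"),
    c("n10", "up1"), c("up1", "cat12"), c("b6", "cat12"),
    c("cat12", "n13"), c("n13", "n14"),
    c("n14", "up2"), c("up2", "cat16"), c("b4", "cat16"),
    c("cat16", "p1_csp"), c("p1_csp", "head_p8"),
    c("p1_csp", "down18"), c("down18", "cat19"), c("n14", "cat19"),
    c("cat19", "p2_csp"), c("p2_csp", "head_p16"),
    c("p2_csp", "down21"), c("down21", "cat22"), c("n10", "cat22"),
    c("cat22", "p3_csp"), c("p3_csp", "head_p32"))
  if (cfg$variant %in% c("SC", "TE", "TC", "FP")) {
    edges <- c(edges, list(
      c("cat16", "skip_p2"), c("skip_p2", "cat19"),
      c("cat16", "skip_p3a"), c("skip_p3a", "skip_p3b"),
      c("skip_p3b", "cat22")))
  }
  tibble::tibble(
    from = vapply(edges, `[`, character(1), 1),
    to = vapply(edges, `[`, character(1), 2))
}

#' Forward pass of a detector
#'
#' @param det a `pn_detector`.
#' @param x numeric 3 x H x W array in `[0, 1]`, H and W even; or an image in
#'   H x W x 3 layout, which is transposed automatically.
#' @param training logical; batch-norm statistics and dropout behave
#'   accordingly.
#' @return list of three raw head outputs (tg nodes) at strides 8, 16, 32,
#'   each (3 * (5 + num_classes)) x H/stride x W/stride, with attributes
#'   `strides`.
#' @export
forward_detector <- function(det, x, training = FALSE) {
  m <- det$mods
  ctx <- list(training = training)
  if (!is_shadow(x) && !is_tg(x)) {
    d <- dim(x)
    if (length(d) == 3 && d[3] == 3L && d[1] != 3L) x <- image_to_tensor(x)
    x <- tg_const(x)
  }
  x2 <- m$b2$fwd(m$b1$fwd(m$focus$fwd(x, ctx), ctx), ctx)
  x4 <- m$b4$fwd(m$b3$fwd(x2, ctx), ctx)
  x6 <- m$b6$fwd(m$b5$fwd(x4, ctx), ctx)
  x9 <- m$b9$fwd(m$spp$fwd(m$b7$fwd(x6, ctx), ctx), ctx)
  t10 <- m$n10$fwd(x9, ctx)
  cat12 <- tg_concat_c(list(op_upsample2(t10), x6))
  x13 <- m$n13$fwd(cat12, ctx)
  t14 <- m$n14$fwd(x13, ctx)
  cat16 <- tg_concat_c(list(op_upsample2(t14), x4))
  p1 <- m$p1_csp$fwd(cat16, ctx)
  d18 <- m$down18$fwd(p1, ctx)
  if (!is.null(m$skip_p2)) d18 <- tg_add(d18, m$skip_p2$fwd(cat16, ctx))
  cat19 <- tg_concat_c(list(d18, t14))
  p2 <- m$p2_csp$fwd(cat19, ctx)
  d21 <- m$down21$fwd(p2, ctx)
  if (!is.null(m$skip_p3a)) {
    d21 <- tg_add(d21, m$skip_p3b$fwd(m$skip_p3a$fwd(cat16, ctx), ctx))
  }
  cat22 <- tg_concat_c(list(d21, t10))
  p3 <- m$p3_csp$fwd(cat22, ctx)
  out <- list(m$head_p8$fwd(p1, ctx),
              m$head_p16$fwd(p2, ctx),
              m$head_p32$fwd(p3, ctx))
  attr(out, "strides") <- c(8L, 16L, 32L)
  out
}

#' Flat named list of a detector's parameter nodes
#' @param det a `pn_detector`.
#' @export
detector_params <- function(det) {
  out <- list()
  for (nm in names(det$mods)) {
    out <- c(out, module_params(det$mods[[nm]], paste0(nm, ".")))
  }
  out
}

#' Count parameters and forward-pass FLOPs
#'
#' FLOPs follow the 2 x multiply-accumulate convention over the convolution
#' and matrix-multiplication operations of one forward pass at
#' `1 x 3 x input_size x input_size`; the parameter count is exact.
#'
#' @param det a `pn_detector`.
#' @param input_size square input resolution in pixels.
#' @return list with `params` (count) and `flops` (total floating-point
#'   operations).
#' @export
#' @examples
#' set.seed(1)
#' det <- build_model(model_config(variant = "baseline", input_size = 64))
#' count_params_flops(det, 64)
count_params_flops <- function(det, input_size = det$cfg$input_size) {
  params <- sum(vapply(detector_params(det),
                       function(p) length(tg_value(p)), numeric(1)))
  tg_reset_macs()
  forward_detector(det, tg_shadow(c(3L, input_size, input_size)))
  list(params = params, flops = 2 * tg_get_macs())
}

#' Extract detector weights as a named list of arrays
#' @param det a `pn_detector`.
#' @export
detector_weights <- function(det) {
  lapply(detector_params(det), tg_value)
}

#' Load weights into a detector, skipping shape mismatches
#'
#' Matching layer names with matching shapes are loaded; everything else is
#' skipped and reported, which makes transfer from a baseline variant into an
#' extended variant possible (new neck blocks stay at their initialization).
#'
#' @param det a `pn_detector`.
#' @param weights named list of arrays (from [detector_weights()]) or a path
#'   to an RDS file containing one.
#' @return `det`, with attribute `"load_report"`: tibble of parameter names
#'   and status (`loaded` / `shape_mismatch` / `missing`).
#' @export
load_pretrained <- function(det, weights) {
  if (is.character(weights)) {
    weights <- tryCatch(readRDS(weights), error = function(e) {
      stop("cannot read weights file: ", conditionMessage(e))
    })
  }
  if (!is.list(weights) || is.null(names(weights))) {
    stop("weights must be a named list of arrays")
  }
  params <- detector_params(det)
  status <- character(length(params))
  names(status) <- names(params)
  for (nm in names(params)) {
    if (is.null(weights[[nm]])) {
      status[nm] <- "missing"
    } else if (!identical(dim_or_len(weights[[nm]]), dim_or_len(tg_value(params[[nm]])))) {
      status[nm] <- "shape_mismatch"
    } else {
      params[[nm]]$value <- weights[[nm]]
      status[nm] <- "loaded"
    }
  }
  attr(det, "load_report") <- tibble::tibble(param = names(status), status = unname(status))
  det
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Convert an H x W x 3 image array to the 3 x H x W tensor layout
#' @param img numeric array, values in `[0, 1]`.
#' @export
image_to_tensor <- function(img) {
  aperm(img, c(3, 1, 2))
}

#' @export
print.pn_detector <- function(x, ...) {
  pf <- count_params_flops(x)
  cat(sprintf("<pn_detector> variant=%s  input=%d  params=%s  GFLOPs=%.1f\n",
              x$cfg$variant, x$cfg$input_size,
              format(pf$params, big.mark = ","), pf$flops / 1e9))
  invisible(x)
}

#' @export
print.pn_config <- function(x, ...) {
  cat(sprintf("<pn_config> variant=%s depth=%.2f width=%.2f classes=%d input=%d\n",
              x$variant, x$depth_multiple, x$width_multiple,
              x$num_classes, x$input_size))
  invisible(x)
}
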