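# Network building blocks: CBS (conv + batch norm + SiLU), Focus,
# cross-stage-partial blocks (CSP1 with residual units, CSP2 without),
# spatial pyramid pooling, the shape-preserving transformer encoder,
# attentional feature fusion (AFF), and the fusion CSP block (CSP-FF) whose
# parallel paths are a convolutional branch and a transformer branch.
#
# A module is a list: $type, $params (named tg nodes), $children (named
# modules), $fwd(x, ctx) with ctx$training driving batch-norm statistics and
# dropout. Parameters persist across forward calls; the tape is rebuilt each
# call.

new_module <- function(type, params = list(), children = list(), fwd,
                       meta = list()) {
  structure(list(type = type, params = params, children = children,
                 fwd = fwd, meta = meta),
            class = "pn_module")
}

#' Collect all parameter nodes of a module tree, named by path
#' @keywords internal
module_params <- function(m, prefix = "") {
  out <- list()
  if (length(m$params)) {
    nm <- paste0(prefix, names(m$params))
    out <- stats::setNames(m$params, nm)
  }
  for (cn in names(m$children)) {
    out <- c(out, module_params(m$children[[cn]], paste0(prefix, cn, ".")))
  }
  out
}

#' Number of trainable parameters in a module tree
#' @keywords internal
module_n_params <- function(m) {
  sum(vapply(module_params(m), function(p) length(tg_value(p)), numeric(1)))
}

conv_init <- function(cout, cin, k) {
  # He initialization for SiLU/ReLU-family activations
  matrix(stats::rnorm(cout * cin * k * k, sd = sqrt(2 / (cin * k * k))),
         nrow = cout)
}

bn_state <- function(c, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(c)
  e$running_var <- rep(1, c)
  e$momentum <- momentum
  e$eps <- eps
  e
}

#' Conv + batch norm + SiLU block
#' @keywords internal
cbs_block <- function(cin, cout, k = 1L, stride = 1L) {
  w <- tg_param(conv_init(cout, cin, k))
  gamma <- tg_param(rep(1, cout))
  beta <- tg_param(numeric(cout))
  st <- bn_state(cout)
  m <- new_module("cbs",
    params = list(w = w, bn_g = gamma, bn_b = beta),
    meta = list(cin = cin, cout = cout, k = k, stride = stride),
    fwd = function(x, ctx) {
      y <- op_conv2d(x, w, NULL, k = k, stride = stride)
      y <- op_batchnorm(y, gamma, beta, st, isTRUE(ctx$training))
      tg_silu(y)
    })
  m$state <- list(bn = st)
  m
}

#' Plain biased convolution (detection head output layer)
#' @keywords internal
conv_bias_block <- function(cin, cout, k = 1L, stride = 1L) {
  w <- tg_param(conv_init(cout, cin, k))
  b <- tg_param(numeric(cout))
  new_module("conv",
    params = list(w = w, b = b),
    meta = list(cin = cin, cout = cout, k = k, stride = stride),
    fwd = function(x, ctx) op_conv2d(x, w, b, k = k, stride = stride))
}

#' Focus block: space-to-depth slicing followed by a CBS convolution
#'
#' Halves the spatial dimensions losslessly (every input value survives the
#' rearrangement) before the convolution mixes the four phases.
#' @keywords internal
focus_block <- function(cin, cout, k = 3L) {
  cv <- cbs_block(4L * cin, cout, k = k, stride = 1L)
  new_module("focus", children = list(cv = cv),
    meta = list(cin = cin, cout = cout),
    fwd = function(x, ctx) cv$fwd(op_space_to_depth(x), ctx))
}

bottleneck_unit <- function(c, shortcut = TRUE) {
  cv1 <- cbs_block(c, c, 1L)
  cv2 <- cbs_block(c, c, 3L)
  new_module("bottleneck", children = list(cv1 = cv1, cv2 = cv2),
    meta = list(shortcut = shortcut),
    fwd = function(x, ctx) {
      y <- cv2$fwd(cv1$fwd(x, ctx), ctx)
      if (shortcut) tg_add(x, y) else y
    })
}

#' Cross-stage-partial block
#'
#' Splits the input into a feature-extraction path (`n` residual units for
#' CSP1, plain bottlenecks without residual addition for CSP2) and a
#' cross-stage path, concatenates and mixes them with a 1x1 convolution.
#' @param kind "CSP1" (backbone, residual units) or "CSP2" (neck).
#' @keywords internal
csp_block <- function(cin, cout, n = 1L, kind = c("CSP1", "CSP2")) {
  kind <- match.arg(kind)
  if (kind == "CSP1" && n < 1L) stop("CSP1 requires n >= 1 residual units")
  n <- max(1L, as.integer(n))
  ch <- cout %/% 2L
  cv1 <- cbs_block(cin, ch, 1L)
  cv2 <- cbs_block(cin, ch, 1L)
  units <- lapply(seq_len(n), function(i) bottleneck_unit(ch, kind == "CSP1"))
  names(units) <- paste0("m", seq_len(n))
  cv3 <- cbs_block(2L * ch, cout, 1L)
  new_module(tolower(kind),
    children = c(list(cv1 = cv1, cv2 = cv2), units, list(cv3 = cv3)),
    meta = list(cin = cin, cout = cout, n = n, kind = kind),
    fwd = function(x, ctx) {
      a <- cv1$fwd(x, ctx)
      for (u in units) a <- u$fwd(a, ctx)
      b <- cv2$fwd(x, ctx)
      cv3$fwd(tg_concat_c(list(a, b)), ctx)
    })
}

#' Spatial pyramid pooling block
#'
#' Identity plus three same-padding max-pool branches, concatenated and
#' mixed; spatial size is preserved.
#' @keywords internal
spp_block <- function(cin, cout, kernels = c(5L, 9L, 13L)) {
  ch <- cin %/% 2L
  cv1 <- cbs_block(cin, ch, 1L)
  cv2 <- cbs_block(ch * (1L + length(kernels)), cout, 1L)
  new_module("spp", children = list(cv1 = cv1, cv2 = cv2),
    meta = list(cin = cin, cout = cout, kernels = kernels),
    fwd = function(x, ctx) {
      y <- cv1$fwd(x, ctx)
      branches <- c(list(y), lapply(kernels, function(k) op_maxpool_same(y, k)))
      cv2$fwd(tg_concat_c(branches), ctx)
    })
}

linear_init <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, sd = sqrt(2 / (cin + cout))), nrow = cin)
}

#' Shape-preserving transformer encoder block
#'
#' Two sublayers with residual addition: multi-head self-attention over the
#' flattened spatial grid (no positional encoding), then a convolutional
#' feed-forward sublayer (two pointwise convolutions, expansion ratio 4) with
#' dropout. Batch normalization precedes each sublayer. Output shape equals
#' input shape, so the block can sit at any point of the network.
#' @keywords internal
transformer_encoder <- function(c, heads = 4L, dropout = 0.1, expansion = 4L) {
  if (c %% heads != 0L) {
    stop("transformer encoder: channels (", c,
         ") must be divisible by the number of heads (", heads, ")")
  }
  dh <- c %/% heads
  wq <- tg_param(linear_init(c, c)); bq <- tg_param(numeric(c))
  wk <- tg_param(linear_init(c, c)); bk <- tg_param(numeric(c))
  wv <- tg_param(linear_init(c, c)); bv <- tg_param(numeric(c))
  wo <- tg_param(linear_init(c, c)); bo <- tg_param(numeric(c))
  n1_g <- tg_param(rep(1, c)); n1_b <- tg_param(numeric(c)); n1_st <- bn_state(c)
  ff1 <- cbs_block(c, expansion * c, 1L)
  ff2w <- tg_param(conv_init(c, expansion * c, 1L))
  ff2g <- tg_param(rep(1, c)); ff2b <- tg_param(numeric(c)); ff2_st <- bn_state(c)
  m <- new_module("transformer_encoder",
    params = list(wq = wq, bq = bq, wk = wk, bk = bk, wv = wv, bv = bv,
                  wo = wo, bo = bo, n1_g = n1_g, n1_b = n1_b,
                  ff2_w = ff2w, ff2_g = ff2g, ff2_b = ff2b),
    children = list(ff1 = ff1),
    meta = list(c = c, heads = heads, dropout = dropout),
    fwd = function(x, ctx) {
      training <- isTRUE(ctx$training)
      d <- if (is_shadow(x)) shadow_dims(x) else dim(tg_value(x))
      n_tok <- d[2] * d[3]
      xn <- op_batchnorm(x, n1_g, n1_b, n1_st, training)
      tokens <- tg_t(tg_reshape(xn, c(c, n_tok)))          # N x C
      q <- tg_add_rowvec(tg_matmul(tokens, wq), bq)
      k <- tg_add_rowvec(tg_matmul(tokens, wk), bk)
      v <- tg_add_rowvec(tg_matmul(tokens, wv), bv)
      outs <- vector("list", heads)
      for (h in seq_len(heads)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        qh <- tg_cols(q, cols); kh <- tg_cols(k, cols); vh <- tg_cols(v, cols)
        scores <- tg_scale(tg_matmul(qh, tg_t(kh)), 1 / sqrt(dh))
        if (is_shadow(scores)) {
          outs[[h]] <- tg_shadow(c(n_tok, dh))
          tg_add_macs(as.numeric(n_tok) * n_tok * dh)      # attn %*% v
          next
        }
        outs[[h]] <- tg_matmul(tg_softmax_rows(scores), vh)
      }
      att <- tg_add_rowvec(tg_matmul(tg_cbind(outs), wo), bo)
      att <- tg_dropout(att, dropout, training)
      y <- if (is_shadow(x)) x else
        tg_add(x, tg_reshape(tg_t(att), c(c, d[2], d[3])))
      # convolutional feed-forward sublayer
      z <- ff1$fwd(y, ctx)
      z <- op_conv2d(z, ff2w, NULL, k = 1L)
      z <- op_batchnorm(z, ff2g, ff2b, ff2_st, training)
      z <- if (is_shadow(z)) z else {
        zd <- tg_dropout(tg_reshape(z, c(c, n_tok)), dropout, training)
        tg_reshape(zd, c(c, d[2], d[3]))
      }
      tg_add(y, z)
    })
  m$state <- list(n1 = n1_st, ff2 = ff2_st)
  m
}

#' Attentional feature fusion of two equal-shape feature maps
#'
#' Computes `M(X + Y) * X + (1 - M(X + Y)) * Y` where M is a sigmoid
#' multi-scale channel attention: a local branch (pointwise-convolution
#' bottleneck over the full map) plus a global branch (globally pooled
#' context through the same bottleneck shape), summed before the sigmoid.
#' The output is an elementwise convex combination of X and Y.
#' @keywords internal
aff_fuse <- function(c, reduction = 4L) {
  cr <- max(4L, c %/% reduction)
  l1 <- cbs_block(c, cr, 1L)                 # local branch bottleneck
  l2w <- tg_param(conv_init(c, cr, 1L))
  l2g <- tg_param(rep(1, c)); l2b <- tg_param(numeric(c)); l2_st <- bn_state(c)
  g1w <- tg_param(linear_init(c, cr)); g1b <- tg_param(numeric(cr))
  g2w <- tg_param(linear_init(cr, c)); g2b <- tg_param(numeric(c))
  m <- new_module("aff",
    params = list(l2_w = l2w, l2_g = l2g, l2_b = l2b,
                  g1_w = g1w, g1_b = g1b, g2_w = g2w, g2_b = g2b),
    children = list(l1 = l1),
    meta = list(c = c, reduction = reduction),
    fwd = function(xy, ctx) {
      x <- xy[[1]]; y <- xy[[2]]
      if (!is_shadow(x)) {
        dx <- dim(tg_value(x)); dy <- dim(tg_value(y))
        if (!identical(dx, dy)) {
          stop("aff_fuse: shape mismatch between X (", paste(dx, collapse = "x"),
               ") and Y (", paste(dy, collapse = "x"), ")")
        }
      }
      s <- tg_add(x, y)
      loc <- l1$fwd(s, ctx)
      loc <- op_conv2d(loc, l2w, NULL, k = 1L)
      loc <- op_batchnorm(loc, l2g, l2b, l2_st, isTRUE(ctx$training))
      g <- op_global_avgpool(s)                       # length-C vector
      if (is_shadow(g)) {
        tg_add_macs(c * cr * 2)
        return(x)
      }
      gv <- tg_matmul(tg_reshape(g, c(1L, c)), g1w)   # 1 x cr
      gv <- tg_relu(tg_add_rowvec(gv, g1b))
      gv <- tg_add_rowvec(tg_matmul(gv, g2w), g2b)    # 1 x C
      mmap <- tg_sigmoid(tg_bc_add(loc, tg_reshape(gv, c)))
      tg_add(tg_mul(mmap, x),
             tg_mul(tg_shift(tg_neg(mmap), 1), y))
    })
  m$state <- list(l2 = l2_st)
  m
}

#' Fusion CSP block (CSP-FF)
#'
#' A CSP2 variant whose two parallel paths are a convolutional path (local
#' features) and a transformer-encoder path (global features), fused by
#' attentional feature fusion, then balanced by a 1x1 convolution. Input and
#' output shapes agree.
#' @keywords internal
csp_ff <- function(cin, cout, heads = 4L, dropout = 0.1) {
  ch <- cout %/% 2L
  cv_t <- cbs_block(cin, ch, 1L)
  te <- transformer_encoder(ch, heads = heads, dropout = dropout)
  cv_c1 <- cbs_block(cin, ch, 1L)
  cv_c2 <- cbs_block(ch, ch, 3L)
  fuse <- aff_fuse(ch)
  cv_out <- cbs_block(ch, cout, 1L)
  new_module("csp_ff",
    children = list(cv_t = cv_t, te = te, cv_c1 = cv_c1, cv_c2 = cv_c2,
                    fuse = fuse, cv_out = cv_out),
    meta = list(cin = cin, cout = cout),
    fwd = function(x, ctx) {
      gl <- te$fwd(cv_t$fwd(x, ctx), ctx)             # transformer path (Y)
      lo <- cv_c2$fwd(cv_c1$fwd(x, ctx), ctx)         # convolutional path (X)
      cv_out$fwd(fuse$fwd(list(lo, gl), ctx), ctx)
    })
}
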