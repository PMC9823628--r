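# Tensor-level neural-network primitives: im2col convolution, batch
# normalization, same-padding max pooling, nearest-neighbour upsampling.
# All operate on C x H x W arrays wrapped in tape nodes, with a shape-only
# shadow path used for profiling.

.nn_cache <- new.env(parent = emptyenv())

# Index matrix mapping a zero-padded (C, Hp, Wp) array onto im2col layout:
# rows ordered channel-fastest then kernel row then kernel column; columns
# ordered output-row-fastest. Cached per shape signature.
im2col_index <- function(cin, h, w, k, stride, pad) {
  key <- paste(cin, h, w, k, stride, pad, sep = "x")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  ci <- rep(seq_len(cin), times = k * k)
  ki <- rep(rep(seq_len(k), each = cin), times = k)
  kj <- rep(seq_len(k), each = cin * k)
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  hi <- outer(ki, (oi - 1L) * stride, `+`)           # R x N input row
  wi <- outer(kj, (oj - 1L) * stride, `+`)           # R x N input col
  idx <- matrix(ci, nrow = length(ci), ncol = length(oi)) +
    cin * (hi - 1L) + cin * hp * (wi - 1L)
  out <- list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp)
  .nn_cache[[key]] <- out
  out
}

#' 2-D convolution (cross-correlation) of a C x H x W map
#'
#' @param x tg node or shadow, C x H x W.
#' @param w tg parameter node, matrix (c_out) x (c_in * k * k) in im2col row
#'   order.
#' @param b tg parameter node, length c_out bias, or NULL.
#' @param k kernel size, odd.
#' @param stride integer stride.
#' @param pad zero padding (defaults to k %/% 2, "same" for stride 1).
#' @keywords internal
op_conv2d <- function(x, w, b = NULL, k = 1L, stride = 1L, pad = k %/% 2L) {
  wv <- tg_value(w)
  cout <- nrow(wv)
  if (is_shadow(x)) {
    d <- shadow_dims(x)
    ho <- (d[2] + 2L * pad - k) %/% stride + 1L
    wo <- (d[3] + 2L * pad - k) %/% stride + 1L
    tg_add_macs(as.numeric(ncol(wv)) * cout * ho * wo)
    return(tg_shadow(c(cout, ho, wo)))
  }
  xv <- tg_value(x)
  d <- dim(xv)
  cin <- d[1]
  stopifnot(ncol(wv) == cin * k * k)
  ii <- im2col_index(cin, d[2], d[3], k, stride, pad)
  if (pad > 0L) {
    xp <- array(0, c(cin, ii$hp, ii$wp))
    xp[, pad + seq_len(d[2]), pad + seq_len(d[3])] <- xv
  } else xp <- xv
  cols <- xp[ii$idx]
  dim(cols) <- dim(ii$idx)
  out <- wv %*% cols
  bv <- if (!is.null(b)) tg_value(b) else NULL
  if (!is.null(bv)) out <- out + bv
  dim(out) <- c(cout, ii$ho, ii$wo)

  px <- if (is_tg(x)) x else tg_const(xv)
  parents <- list(px, w)
  if (!is.null(b)) parents <- c(parents, list(b))
  tg_node(out, parents, function(grad) {
    gmat <- matrix(grad, nrow = cout)
    dW <- NULL; dx <- NULL; db <- NULL
    if (w$requires_grad) {
      cols2 <- xp[ii$idx]
      dim(cols2) <- dim(ii$idx)
      dW <- tcrossprod(gmat, cols2)
    }
    if (px$requires_grad) {
      dcols <- crossprod(wv, gmat)                    # R x N
      dxp <- array(0, c(cin, ii$hp, ii$wp))
      nblk <- k * k
      for (bi in seq_len(nblk)) {
        rows <- (bi - 1L) * cin + seq_len(cin)
        idxb <- ii$idx[rows, , drop = FALSE]
        dxp[idxb] <- dxp[idxb] + dcols[rows, , drop = FALSE]
      }
      dx <- dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), drop = FALSE]
      dim(dx) <- d
    }
    if (!is.null(b) && b$requires_grad) db <- rowSums(gmat)
    out <- list(dx, dW)
    if (!is.null(b)) out <- c(out, list(db))
    out
  })
}

#' Per-channel normalization over the spatial dimensions
#'
#' Normalizes each channel by the current map's spatial mean and variance at
#' both training and evaluation time. The engine forwards one image per
#' pass (gradients are accumulated over the batch), so per-map statistics
#' are the only normalization both phases can share; batch-style running
#' estimates are still tracked in `state` during training and used only for
#' degenerate 1 x 1 maps.
#' @keywords internal
op_batchnorm <- function(x, gamma, beta, state, training) {
  if (is_shadow(x)) return(x)
  xv <- tg_value(x)
  d <- dim(xv)
  cc <- d[1]; n <- d[2] * d[3]
  xm <- matrix(xv, cc)
  gv <- tg_value(gamma); bv <- tg_value(beta)
  eps <- state$eps
  if (n > 1L) {
    mu <- rowMeans(xm)
    va <- rowMeans((xm - mu)^2)
    if (training) {
      m <- state$momentum
      state$running_mean <- (1 - m) * state$running_mean + m * mu
      state$running_var <- (1 - m) * state$running_var + m * va * n / max(n - 1L, 1L)
    }
    training <- TRUE          # normalization backward uses map statistics
  } else {
    mu <- state$running_mean
    va <- state$running_var
    training <- FALSE
  }
  sd_inv <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * sd_inv
  out <- gv * xhat + bv
  dim(out) <- d
  px <- if (is_tg(x)) x else tg_const(xv)
  tg_node(out, list(px, gamma, beta), function(grad) {
    gm <- matrix(grad, cc)
    dgamma <- if (gamma$requires_grad) rowSums(gm * xhat) else NULL
    dbeta <- if (beta$requires_grad) rowSums(gm) else NULL
    dx <- NULL
    if (px$requires_grad) {
      dxhat <- gm * gv
      if (training) {
        # full batch-stats backward
        t1 <- rowSums(dxhat)
        t2 <- rowSums(dxhat * xhat)
        dxm <- sd_inv * (dxhat - t1 / n - xhat * t2 / n)
      } else {
        dxm <- dxhat * sd_inv
      }
      dx <- dxm
      dim(dx) <- d
    }
    list(dx, dgamma, dbeta)
  })
}

#' Same-padding stride-1 max pooling (spatial pyramid pooling branches)
#' @keywords internal
op_maxpool_same <- function(x, k) {
  if (is_shadow(x)) return(x)
  xv <- tg_value(x)
  d <- dim(xv)
  pad <- k %/% 2L
  cc <- d[1]; h <- d[2]; w <- d[3]
  hp <- h + 2L * pad; wp <- w + 2L * pad
  xp <- array(-Inf, c(cc, hp, wp))
  xp[, pad + seq_len(h), pad + seq_len(w)] <- xv
  out <- array(-Inf, d)
  arg <- array(0L, d)
  key <- paste("mp", cc, h, w, k, sep = "x")
  lins <- .nn_cache[[key]]
  if (is.null(lins)) {
    base_c <- rep(seq_len(cc), times = h * w)
    base_h <- rep(rep(seq_len(h), each = cc), times = w)
    base_w <- rep(seq_len(w), each = cc * h)
    base <- base_c + cc * (base_h - 1L) + cc * hp * (base_w - 1L)
    lins <- lapply(seq_len(k * k), function(b) {
      ki <- (b - 1L) %% k
      kj <- (b - 1L) %/% k
      base + cc * ki + cc * hp * kj
    })
    .nn_cache[[key]] <- lins
  }
  for (lin in lins) {
    slice <- xp[lin]
    upd <- slice > out
    out[upd] <- slice[upd]
    arg[upd] <- lin[upd]
  }
  px <- if (is_tg(x)) x else tg_const(xv)
  tg_node(out, list(px), function(grad) {
    dxp <- numeric(cc * hp * wp)
    acc <- rowsum(as.vector(grad), as.vector(arg))
    dxp[as.numeric(rownames(acc))] <- acc
    dim(dxp) <- c(cc, hp, wp)
    dx <- dxp[, pad + seq_len(h), pad + seq_len(w), drop = FALSE]
    dim(dx) <- d
    list(dx)
  })
}

#' Nearest-neighbour 2x upsampling
#' @keywords internal
op_upsample2 <- function(x) {
  if (is_shadow(x)) {
    d <- shadow_dims(x)
    return(tg_shadow(c(d[1], d[2] * 2L, d[3] * 2L)))
  }
  xv <- tg_value(x)
  d <- dim(xv)
  hi <- rep(seq_len(d[2]), each = 2L)
  wi <- rep(seq_len(d[3]), each = 2L)
  out <- xv[, hi, wi, drop = FALSE]
  dim(out) <- c(d[1], 2L * d[2], 2L * d[3])
  px <- if (is_tg(x)) x else tg_const(xv)
  tg_node(out, list(px), function(grad) {
    odd_h <- seq(1L, 2L * d[2], by = 2L); odd_w <- seq(1L, 2L * d[3], by = 2L)
    dx <- grad[, odd_h, odd_w, drop = FALSE] +
      grad[, odd_h + 1L, odd_w, drop = FALSE] +
      grad[, odd_h, odd_w + 1L, drop = FALSE] +
      grad[, odd_h + 1L, odd_w + 1L, drop = FALSE]
    dim(dx) <- d
    list(dx)
  })
}

#' Space-to-depth slicing: C x H x W -> 4C x H/2 x W/2 (the Focus rearrange)
#' @keywords internal
op_space_to_depth <- function(x) {
  if (is_shadow(x)) {
    d <- shadow_dims(x)
    return(tg_shadow(c(4L * d[1], d[2] %/% 2L, d[3] %/% 2L)))
  }
  xv <- tg_value(x)
  d <- dim(xv)
  if (d[2] %% 2L != 0L || d[3] %% 2L != 0L) {
    stop("space-to-depth slicing requires even spatial dimensions, got ",
         d[2], " x ", d[3])
  }
  oh <- seq(1L, d[2], by = 2L); ow <- seq(1L, d[3], by = 2L)
  eh <- oh + 1L; ew <- ow + 1L
  parts <- list(
    xv[, oh, ow, drop = FALSE], xv[, eh, ow, drop = FALSE],
    xv[, oh, ew, drop = FALSE], xv[, eh, ew, drop = FALSE])
  out <- array(0, c(4L * d[1], d[2] %/% 2L, d[3] %/% 2L))
  for (i in 1:4) out[(i - 1L) * d[1] + seq_len(d[1]), , ] <- parts[[i]]
  px <- if (is_tg(x)) x else tg_const(xv)
  tg_node(out, list(px), function(grad) {
    dx <- array(0, d)
    sel <- list(list(oh, ow), list(eh, ow), list(oh, ew), list(eh, ew))
    for (i in 1:4) {
      dx[, sel[[i]][[1]], sel[[i]][[2]]] <-
        grad[(i - 1L) * d[1] + seq_len(d[1]), , , drop = FALSE]
    }
    list(dx)
  })
}

#' Global average pool to a per-channel vector
#' @keywords internal
op_global_avgpool <- function(x) {
  if (is_shadow(x)) return(tg_shadow(shadow_dims(x)[1]))
  xv <- tg_value(x)
  d <- dim(xv)
  n <- d[2] * d[3]
  val <- rowMeans(matrix(xv, d[1]))
  px <- if (is_tg(x)) x else tg_const(xv)
  tg_node(val, list(px), function(grad) {
    g <- array(rep(grad / n), d)
    list(g)
  })
}
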