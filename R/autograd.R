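# Reverse-mode automatic differentiation over base R numeric arrays.
#
# Every value on the tape is a `tg` node: an environment holding the numeric
# array, its parents, and a closure that maps the node's upstream gradient to
# gradients for each parent. backward() seeds the root and walks the graph in
# reverse topological order. A parallel "shadow" mode propagates shapes only
# and accumulates multiply-accumulate counts, so the exact forward wiring
# doubles as the FLOP profiler.

.tg_env <- new.env(parent = emptyenv())
.tg_env$id <- 0L
.tg_env$macs <- 0

tg_next_id <- function() {
  .tg_env$id <- .tg_env$id + 1L
  .tg_env$id
}

#' Create a tape node
#'
#' @param value numeric array/matrix/vector.
#' @param parents list of parent `tg` nodes.
#' @param backfn function(grad) returning a list of gradients, one per parent
#'   (NULL for parents that need no gradient).
#' @param requires_grad logical; leaves default to FALSE.
#' @return a `tg` node.
#' @keywords internal
tg_node <- function(value, parents = list(), backfn = NULL, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$id <- tg_next_id()
  if (length(parents)) {
    requires_grad <- any(vapply(parents, function(p) p$requires_grad, logical(1)))
  }
  e$requires_grad <- requires_grad
  class(e) <- "tg"
  e
}

#' @keywords internal
tg_const <- function(value) tg_node(value)

#' Create a trainable parameter node
#' @keywords internal
tg_param <- function(value) tg_node(value, requires_grad = TRUE)

is_tg <- function(x) inherits(x, "tg")

#' @keywords internal
tg_value <- function(x) if (is_tg(x)) x$value else x

# ---- shadow (shape-only) tensors -------------------------------------------

#' @keywords internal
tg_shadow <- function(dims) structure(list(dims = as.integer(dims)), class = "tg_shadow")

is_shadow <- function(x) inherits(x, "tg_shadow")

shadow_dims <- function(x) x$dims

#' @keywords internal
tg_reset_macs <- function() .tg_env$macs <- 0

#' @keywords internal
tg_add_macs <- function(n) .tg_env$macs <- .tg_env$macs + n

#' @keywords internal
tg_get_macs <- function() .tg_env$macs

# ---- backward pass ----------------------------------------------------------

#' Run backpropagation from a scalar root node
#'
#' Accumulates gradients into `$grad` of every node with `requires_grad`.
#' @keywords internal
tg_backward <- function(root, seed = 1) {
  if (!is_tg(root)) stop("backward needs a tg node")
  # iterative topological sort over the requires_grad subgraph
  order <- vector("list", 256L)
  n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$requires_grad && is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  if (n_ord == 0L) return(invisible(NULL))
  order <- order[seq_len(n_ord)]
  root$grad <- if (is.null(dim(root$value))) {
    rep(seed, length(root$value))
  } else {
    array(seed, dim = dim(root$value))
  }
  # reverse topological order: root last in post-order list
  for (i in rev(seq_len(n_ord))) {
    node <- order[[i]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    grads <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      g <- grads[[j]]
      if (is.null(g) || !p$requires_grad) next
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
    }
  }
  invisible(NULL)
}

#' Zero the gradients of a list of parameter nodes
#' @keywords internal
tg_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise binary ops -------------------------------------------------

tg_ew2 <- function(a, b, f, dfa, dfb) {
  sa <- is_shadow(a)          # force both promises: shadow-mode profiling
  sb <- is_shadow(b)          # must execute both operand subgraphs
  if (sa || sb) {
    return(tg_shadow(if (sa) a$dims else b$dims))
  }
  av <- tg_value(a); bv <- tg_value(b)
  pa <- if (is_tg(a)) a else tg_const(av)
  pb <- if (is_tg(b)) b else tg_const(bv)
  val <- f(av, bv)
  tg_node(val, list(pa, pb), function(grad) {
    list(if (pa$requires_grad) dfa(grad, av, bv, val) else NULL,
         if (pb$requires_grad) dfb(grad, av, bv, val) else NULL)
  })
}

#' @keywords internal
tg_add <- function(a, b) tg_ew2(a, b, `+`,
  function(g, av, bv, v) g, function(g, av, bv, v) g)

#' @keywords internal
tg_sub <- function(a, b) tg_ew2(a, b, `-`,
  function(g, av, bv, v) g, function(g, av, bv, v) -g)

#' @keywords internal
tg_mul <- function(a, b) tg_ew2(a, b, `*`,
  function(g, av, bv, v) g * bv, function(g, av, bv, v) g * av)

#' @keywords internal
tg_div <- function(a, b) tg_ew2(a, b, `/`,
  function(g, av, bv, v) g / bv, function(g, av, bv, v) -g * av / (bv * bv))

#' @keywords internal
tg_pmin <- function(a, b) tg_ew2(a, b, pmin,
  function(g, av, bv, v) g * (av <= bv), function(g, av, bv, v) g * (bv < av))

#' @keywords internal
tg_pmax <- function(a, b) tg_ew2(a, b, pmax,
  function(g, av, bv, v) g * (av >= bv), function(g, av, bv, v) g * (bv > av))

# ---- elementwise unary ops --------------------------------------------------

tg_ew1 <- function(x, f, df) {
  if (is_shadow(x)) return(x)
  xv <- tg_value(x)
  px <- if (is_tg(x)) x else tg_const(xv)
  val <- f(xv)
  tg_node(val, list(px), function(grad) list(grad * df(xv, val)))
}

#' @keywords internal
tg_neg <- function(x) tg_ew1(x, function(v) -v, function(xv, v) -1)

#' @keywords internal
tg_square <- function(x) tg_ew1(x, function(v) v * v, function(xv, v) 2 * xv)

#' @keywords internal
tg_sqrt <- function(x) tg_ew1(x, sqrt, function(xv, v) 0.5 / pmax(v, 1e-12))

#' @keywords internal
tg_exp <- function(x) tg_ew1(x, exp, function(xv, v) v)

sigm <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
tg_sigmoid <- function(x) tg_ew1(x, sigm, function(xv, v) v * (1 - v))

#' @keywords internal
tg_silu <- function(x) tg_ew1(x, function(v) v * sigm(v),
  function(xv, v) {
    s <- sigm(xv)
    s * (1 + xv * (1 - s))
  })

#' @keywords internal
tg_scale <- function(x, k) tg_ew1(x, function(v) v * k, function(xv, v) k)

#' @keywords internal
tg_shift <- function(x, k) tg_ew1(x, function(v) v + k, function(xv, v) 1)

#' @keywords internal
tg_relu <- function(x) tg_ew1(x, function(v) pmax(v, 0), function(xv, v) (xv > 0) * 1)

# ---- reductions -------------------------------------------------------------

#' @keywords internal
tg_sum <- function(x) {
  if (is_shadow(x)) return(tg_shadow(1L))
  xv <- tg_value(x)
  px <- if (is_tg(x)) x else tg_const(xv)
  d <- dim(xv)
  tg_node(sum(xv), list(px), function(grad) {
    g <- array(grad, dim = if (is.null(d)) length(xv) else d)
    if (is.null(d)) g <- as.vector(g)
    list(g)
  })
}

#' @keywords internal
tg_mean <- function(x) {
  n <- if (is_shadow(x)) prod(x$dims) else length(tg_value(x))
  tg_scale(tg_sum(x), 1 / n)
}

# ---- structural ops ---------------------------------------------------------

#' Concatenate feature maps along the channel (first) dimension
#' @keywords internal
tg_concat_c <- function(xs) {
  if (any(vapply(xs, is_shadow, logical(1)))) {
    dims <- lapply(xs, shadow_dims)
    c_tot <- sum(vapply(dims, function(d) d[1], integer(1)))
    return(tg_shadow(c(c_tot, dims[[1]][2], dims[[1]][3])))
  }
  vals <- lapply(xs, tg_value)
  dims <- lapply(vals, dim)
  h <- dims[[1]][2]; w <- dims[[1]][3]
  cs <- vapply(dims, function(d) d[1], numeric(1))
  out <- array(0, c(sum(cs), h, w))
  at <- 0L
  for (i in seq_along(vals)) {
    out[at + seq_len(cs[i]), , ] <- vals[[i]]
    at <- at + cs[i]
  }
  parents <- lapply(xs, function(x) if (is_tg(x)) x else tg_const(tg_value(x)))
  tg_node(out, parents, function(grad) {
    at <- 0L
    lapply(seq_along(parents), function(i) {
      g <- grad[at + seq_len(cs[i]), , , drop = FALSE]
      at <<- at + cs[i]
      array(g, c(cs[i], h, w))
    })
  })
}

#' Reshape, preserving element order
#' @keywords internal
tg_reshape <- function(x, dims) {
  if (is_shadow(x)) return(tg_shadow(dims))
  xv <- tg_value(x)
  px <- if (is_tg(x)) x else tg_const(xv)
  old <- dim(xv)
  val <- xv
  dim(val) <- dims
  tg_node(val, list(px), function(grad) {
    g <- grad
    if (is.null(old)) g <- as.vector(g) else dim(g) <- old
    list(g)
  })
}

#' Gather a vector of elements by linear index
#' @keywords internal
tg_gather <- function(x, idx) {
  if (is_shadow(x)) return(tg_shadow(length(idx)))
  xv <- tg_value(x)
  px <- if (is_tg(x)) x else tg_const(xv)
  d <- dim(xv)
  tg_node(xv[idx], list(px), function(grad) {
    g <- array(0, dim = if (is.null(d)) length(xv) else d)
    # indices may repeat: accumulate
    acc <- rowsum(as.vector(grad), idx)
    g[as.numeric(rownames(acc))] <- acc
    list(g)
  })
}

#' Broadcast-add a per-channel vector (C) onto a C x H x W map
#' @keywords internal
tg_bc_add <- function(x, b) {
  if (is_shadow(x)) return(x)
  xv <- tg_value(x); bv <- tg_value(b)
  px <- if (is_tg(x)) x else tg_const(xv)
  pb <- if (is_tg(b)) b else tg_const(bv)
  d <- dim(xv)
  val <- xv + array(bv, d)  # recycles along C fastest: C x H x W ordering
  tg_node(val, list(px, pb), function(grad) {
    list(if (px$requires_grad) grad else NULL,
         if (pb$requires_grad) rowSums(matrix(grad, d[1])) else NULL)
  })
}

#' Broadcast-multiply a per-channel vector (C) over a C x H x W map
#' @keywords internal
tg_bc_mul <- function(x, b) {
  if (is_shadow(x)) return(x)
  xv <- tg_value(x); bv <- tg_value(b)
  px <- if (is_tg(x)) x else tg_const(xv)
  pb <- if (is_tg(b)) b else tg_const(bv)
  d <- dim(xv)
  bfull <- array(bv, d)
  tg_node(xv * bfull, list(px, pb), function(grad) {
    list(if (px$requires_grad) grad * bfull else NULL,
         if (pb$requires_grad) rowSums(matrix(grad * xv, d[1])) else NULL)
  })
}

# ---- matrix ops (for self-attention) ----------------------------------------

#' @keywords internal
tg_matmul <- function(a, b) {
  if (is_shadow(a) || is_shadow(b)) {
    da <- if (is_shadow(a)) a$dims else dim(tg_value(a))
    db <- if (is_shadow(b)) b$dims else dim(tg_value(b))
    tg_add_macs(da[1] * da[2] * db[2])
    return(tg_shadow(c(da[1], db[2])))
  }
  av <- tg_value(a); bv <- tg_value(b)
  pa <- if (is_tg(a)) a else tg_const(av)
  pb <- if (is_tg(b)) b else tg_const(bv)
  tg_node(av %*% bv, list(pa, pb), function(grad) {
    list(if (pa$requires_grad) grad %*% t(bv) else NULL,
         if (pb$requires_grad) t(av) %*% grad else NULL)
  })
}

#' @keywords internal
tg_t <- function(x) {
  if (is_shadow(x)) return(tg_shadow(rev(x$dims)))
  xv <- tg_value(x)
  px <- if (is_tg(x)) x else tg_const(xv)
  tg_node(t(xv), list(px), function(grad) list(t(grad)))
}

#' Row-wise softmax of a matrix
#' @keywords internal
tg_softmax_rows <- function(x) {
  if (is_shadow(x)) return(x)
  xv <- tg_value(x)
  px <- if (is_tg(x)) x else tg_const(xv)
  m <- apply(xv, 1, max)
  e <- exp(xv - m)
  val <- e / rowSums(e)
  tg_node(val, list(px), function(grad) {
    dot <- rowSums(grad * val)
    list(val * (grad - dot))
  })
}

#' Column-subset of a matrix (head split); cols must be a contiguous range
#' @keywords internal
tg_cols <- function(x, cols) {
  if (is_shadow(x)) return(tg_shadow(c(x$dims[1], length(cols))))
  xv <- tg_value(x)
  px <- if (is_tg(x)) x else tg_const(xv)
  d <- dim(xv)
  tg_node(xv[, cols, drop = FALSE], list(px), function(grad) {
    g <- matrix(0, d[1], d[2])
    g[, cols] <- grad
    list(g)
  })
}

#' Column-bind matrices (inverse of head split)
#' @keywords internal
tg_cbind <- function(xs) {
  if (any(vapply(xs, is_shadow, logical(1)))) {
    dims <- lapply(xs, function(x) if (is_shadow(x)) x$dims else dim(tg_value(x)))
    return(tg_shadow(c(dims[[1]][1], sum(vapply(dims, `[`, numeric(1), 2)))))
  }
  vals <- lapply(xs, tg_value)
  ncols <- vapply(vals, ncol, numeric(1))
  parents <- lapply(xs, function(x) if (is_tg(x)) x else tg_const(tg_value(x)))
  tg_node(do.call(cbind, vals), parents, function(grad) {
    at <- 0L
    lapply(seq_along(parents), function(i) {
      g <- grad[, at + seq_len(ncols[i]), drop = FALSE]
      at <<- at + ncols[i]
      g
    })
  })
}

#' Add a length-ncol vector to every row of a matrix (token bias)
#' @keywords internal
tg_add_rowvec <- function(x, b) {
  if (is_shadow(x)) return(x)
  xv <- tg_value(x); bv <- tg_value(b)
  px <- if (is_tg(x)) x else tg_const(xv)
  pb <- if (is_tg(b)) b else tg_const(bv)
  val <- sweep(xv, 2L, bv, `+`)
  tg_node(val, list(px, pb), function(grad) {
    list(if (px$requires_grad) grad else NULL,
         if (pb$requires_grad) colSums(grad) else NULL)
  })
}

#' Dropout (inverted scaling); identity when inactive or p = 0
#' @keywords internal
tg_dropout <- function(x, p, active) {
  if (is_shadow(x) || !active || p <= 0) return(x)
  xv <- tg_value(x)
  px <- if (is_tg(x)) x else tg_const(xv)
  keep <- (stats::runif(length(xv)) >= p) / (1 - p)
  dim(keep) <- dim(xv)
  tg_node(xv * keep, list(px), function(grad) list(grad * keep))
}

#' Mean binary cross-entropy on logits (numerically stable)
#' @keywords internal
tg_bce_logits <- function(logits, targets) {
  if (is_shadow(logits)) return(tg_shadow(1L))
  xv <- tg_value(logits)
  tv <- tg_value(targets)
  px <- if (is_tg(logits)) logits else tg_const(xv)
  n <- length(xv)
  # softplus(x) - x*t, stable for large |x|
  val <- sum(pmax(xv, 0) - xv * tv + log1p(exp(-abs(xv)))) / n
  tg_node(val, list(px), function(grad) {
    g <- grad * (sigm(xv) - tv) / n
    dim(g) <- dim(xv)
    list(g)
  })
}
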