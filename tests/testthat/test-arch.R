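# Structural contracts of the network blocks and the assembled variants.

ns <- asNamespace("pearnet")
ctx_eval <- list(training = FALSE)

test_that("focus block halves space, keeps every value, rejects odd sizes", {
  set.seed(1)
  m <- ns$focus_block(3L, 16L)
  x <- array(runif(3 * 8 * 8), c(3, 8, 8))
  out <- m$fwd(ns$tg_const(x), ctx_eval)
  expect_equal(dim(tgv(out)), c(16, 4, 4))
  # the slicing itself is a lossless rearrangement
  sliced <- tgv(ns$op_space_to_depth(ns$tg_const(x)))
  expect_equal(sort(as.vector(sliced)), sort(as.vector(x)))
  odd <- array(runif(3 * 7 * 8), c(3, 7, 8))
  expect_error(m$fwd(ns$tg_const(odd), ctx_eval), "even spatial")
})

test_that("csp blocks preserve space and grow monotonically with n", {
  set.seed(2)
  for (kind in c("CSP1", "CSP2")) {
    m <- ns$csp_block(16L, 24L, 2L, kind)
    x <- array(rnorm(16 * 6 * 5), c(16, 6, 5))
    expect_equal(dim(tgv(m$fwd(ns$tg_const(x), ctx_eval))), c(24, 6, 5))
  }
  p1 <- ns$module_n_params(ns$csp_block(16L, 16L, 1L, "CSP1"))
  p3 <- ns$module_n_params(ns$csp_block(16L, 16L, 3L, "CSP1"))
  expect_gt(p3, p1)
  # single-pixel degenerate input stays defined
  m <- ns$csp_block(8L, 8L, 1L, "CSP2")
  out <- m$fwd(ns$tg_const(array(rnorm(8), c(8, 1, 1))), ctx_eval)
  expect_equal(dim(tgv(out)), c(8, 1, 1))
  expect_true(all(is.finite(tgv(out))))
})

test_that("spatial pyramid pooling preserves shape; pooling a constant is the constant", {
  set.seed(3)
  m <- ns$spp_block(16L, 16L)
  x <- array(rnorm(16 * 20 * 20), c(16, 20, 20))
  expect_equal(dim(tgv(m$fwd(ns$tg_const(x), ctx_eval))), c(16, 20, 20))
  const <- array(2.5, c(4, 6, 6))
  pooled <- tgv(ns$op_maxpool_same(ns$tg_const(const), 5L))
  expect_equal(pooled, const)
  one <- tgv(ns$op_maxpool_same(ns$tg_const(array(1.5, c(8, 1, 1))), 5L))
  expect_equal(one, array(1.5, c(8, 1, 1)))
})

test_that("transformer encoder is shape-preserving, deterministic at dropout 0,
           and permutation-equivariant without positional encoding", {
  set.seed(4)
  te <- ns$transformer_encoder(8L, heads = 4L, dropout = 0)
  x <- array(rnorm(8 * 2 * 2), c(8, 2, 2))
  o1 <- tgv(te$fwd(ns$tg_const(x), ctx_eval))
  o2 <- tgv(te$fwd(ns$tg_const(x), ctx_eval))
  expect_equal(dim(o1), c(8, 2, 2))
  expect_identical(o1, o2)
  expect_error(ns$transformer_encoder(10L, heads = 4L), "divisible")
  # permuting the four spatial positions and inverse-permuting the output
  # leaves the result unchanged (no positional encoding anywhere)
  perm <- c(3L, 1L, 4L, 2L)
  xm <- matrix(x, 8)                      # channels x tokens
  xp <- array(xm[, perm], c(8, 2, 2))
  op <- matrix(tgv(te$fwd(ns$tg_const(xp), ctx_eval)), 8)
  op_back <- op[, order(perm)]
  expect_equal(op_back, matrix(o1, 8), tolerance = 1e-10)
})

test_that("attentional feature fusion is an elementwise convex combination", {
  set.seed(5)
  af <- ns$aff_fuse(4L)
  for (rep in 1:5) {
    x <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
    y <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
    out <- tgv(af$fwd(list(ns$tg_const(x), ns$tg_const(y)), ctx_eval))
    expect_true(all(out >= pmin(x, y) - 1e-12))
    expect_true(all(out <= pmax(x, y) + 1e-12))
  }
  # X == Y collapses to X for any attention map
  x <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  expect_equal(tgv(af$fwd(list(ns$tg_const(x), ns$tg_const(x)), ctx_eval)), x,
               tolerance = 1e-12)
  expect_error(af$fwd(list(ns$tg_const(x),
                           ns$tg_const(array(0, c(4, 2, 3)))), ctx_eval),
               "shape mismatch")
})

test_that("fusion CSP preserves shape, outweighs plain CSP2, trains both paths", {
  set.seed(6)
  cf <- ns$csp_ff(16L, 16L, heads = 4L, dropout = 0)
  x <- array(rnorm(16 * 4 * 4), c(16, 4, 4))
  expect_equal(dim(tgv(cf$fwd(ns$tg_const(x), ctx_eval))), c(16, 4, 4))
  expect_gt(ns$module_n_params(cf),
            ns$module_n_params(ns$csp_block(16L, 16L, 1L, "CSP2")))
  # gradient reaches both the convolutional and the transformer path
  loss <- ns$tg_sum(ns$tg_square(cf$fwd(ns$tg_const(x), list(training = FALSE))))
  ns$tg_backward(loss)
  pp <- ns$module_params(cf)
  conv_g <- pp[["cv_c2.w"]]$grad
  te_g <- pp[["te.wq"]]$grad
  expect_true(!is.null(conv_g) && sum(abs(conv_g)) > 0)
  expect_true(!is.null(te_g) && sum(abs(te_g)) > 0)
})

test_that("variant wiring follows the ablation plan", {
  expect_error(model_config(variant = "bogus"))
  det <- tiny_detector("FP", 64L)
  out <- forward_detector(det, array(0.5, c(3, 64, 64)))
  expect_equal(lapply(out, function(o) dim(tgv(o))[2:3]),
               list(c(8L, 8L), c(4L, 4L), c(2L, 2L)))
  # parameter monotonicity across variants
  np <- vapply(c("baseline", "SC", "TE", "TC", "FP"), function(v) {
    count_params_flops(tiny_detector(v, 64L), 64)$params
  }, numeric(1))
  expect_lt(np[["baseline"]], np[["SC"]])
  expect_lt(np[["SC"]], np[["TE"]])
  expect_lt(np[["SC"]], np[["TC"]])
  expect_lt(np[["TE"]], np[["FP"]])
  expect_lt(np[["TC"]], np[["FP"]])
})

test_that("the two added skip connections bypass one and two extraction modules", {
  g <- tiny_detector("SC", 64L)$graph
  base <- tiny_detector("baseline", 64L)$graph
  expect_equal(nrow(g) - nrow(base), 5L)  # two skips, one via a mid node
  # count feature-extraction modules (csp blocks) on the shortest stock path
  # between each skip's endpoints
  path_mods <- function(graph, from, to) {
    # breadth-first search over the stock edges
    stock <- graph[!(graph$from %in% c("skip_p2", "skip_p3a", "skip_p3b") |
                     graph$to %in% c("skip_p2", "skip_p3a", "skip_p3b")), ]
    frontier <- list(list(node = from, path = character()))
    seen <- character()
    while (length(frontier)) {
      cur <- frontier[[1]]; frontier <- frontier[-1]
      if (cur$node == to) return(cur$path)
      if (cur$node %in% seen) next
      seen <- c(seen, cur$node)
      nxt <- stock$to[stock$from == cur$node]
      for (n2 in nxt) {
        frontier[[length(frontier) + 1L]] <-
          list(node = n2, path = c(cur$path, n2))
      }
    }
    character()
  }
  p2_path <- path_mods(g, "cat16", "cat19")
  p3_path <- path_mods(g, "cat16", "cat22")
  n_extract <- function(p) sum(p %in% c("p1_csp", "p2_csp", "p3_csp", "n13"))
  expect_equal(n_extract(p2_path), 1L)   # skip into P2 bypasses p1_csp
  expect_equal(n_extract(p3_path), 2L)   # skip into P3 bypasses p1_csp + p2_csp
  # and the skip edges themselves exist
  expect_true(any(g$from == "cat16" & g$to == "skip_p2"))
  expect_true(any(g$from == "skip_p3b" & g$to == "cat22"))
})

test_that("parameter/FLOP counting matches a hand-computed single-layer oracle", {
  ns2 <- asNamespace("pearnet")
  set.seed(9)
  conv <- ns2$conv_bias_block(3L, 16L, 3L)
  expect_equal(ns2$module_n_params(conv), 3 * 3 * 3 * 16 + 16)
  ns2$tg_reset_macs()
  conv$fwd(ns2$tg_shadow(c(3L, 640L, 640L)), ctx_eval)
  flops <- 2 * ns2$tg_get_macs()
  expect_equal(flops, 2 * (3 * 3 * 3) * 16 * 640 * 640)
  expect_equal(flops / 1e8, 3.539, tolerance = 1e-3)
})

test_that("doubling the input side quadruples convolutional FLOPs", {
  det <- tiny_detector("baseline", 64L)
  f64 <- count_params_flops(det, 64)$flops
  f128 <- count_params_flops(det, 128)$flops
  expect_equal(f128 / f64, 4, tolerance = 1e-9)
})

test_that("weight transfer loads matching layers and reports the rest", {
  det_base <- tiny_detector("baseline", 64L)
  set.seed(21)
  det_fp <- build_model(model_config(variant = "FP", input_size = 64,
                                     width_multiple = 0.25))
  x <- array(runif(3 * 64 * 64), c(3, 64, 64))
  # self-load is an identity on the forward pass
  set.seed(22)
  det2 <- build_model(model_config(variant = "baseline", input_size = 64,
                                   width_multiple = 0.25))
  det2 <- load_pretrained(det2, detector_weights(det_base))
  o1 <- tgv(forward_detector(det_base, x)[[1]])
  o2 <- tgv(forward_detector(det2, x)[[1]])
  expect_equal(o1, o2, tolerance = 1e-12)
  # baseline -> FP: backbone loads, new neck blocks are skipped
  det_fp <- load_pretrained(det_fp, detector_weights(det_base))
  rep <- attr(det_fp, "load_report")
  expect_true(all(rep$status[grepl("^b[0-9]\\.|^focus", rep$param)] == "loaded"))
  expect_true(any(rep$status == "missing"))
  suppressWarnings(expect_error(load_pretrained(det_base, tempfile()),
                                "cannot read"))
})
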