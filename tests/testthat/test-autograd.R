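# Gradient correctness of the reverse-mode engine: every op used by the
# detector is checked against central finite differences on small inputs.

# fixed random probe constants (must not change between finite-difference
# evaluations of the same loss)
kc <- local({
  cache <- list()
  function(...) {
    key <- paste(c(...), collapse = "x")
    if (is.null(cache[[key]])) cache[[key]] <<- ns$tt(rnd(...))
    cache[[key]]
  }
})

test_that("elementwise, matmul and reduction gradients match finite differences", {
  set.seed(1)
  a <- tp(rnd(3, 4)); b <- tp(rnd(3, 4))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_add(p[[1]], p[[2]]), ns$t_sub(p[[1]], p[[2]]))),
    list(a, b)), 1e-4)
  w <- tp(rnd(4, 2))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_matmul(p[[1]], p[[2]])), list(a, w)), 1e-4)
  expect_lt(gradcheck(function(p)
    ns$t_mean(ns$t_div(p[[1]], ns$t_add(ns$t_mul(p[[2]], p[[2]]), 1))),
    list(a, b)), 1e-4)
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_abs(ns$t_minimum(p[[1]], p[[2]]))), list(a, b)), 1e-3)
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_maximum(p[[1]], ns$t_clamp_min(p[[2]], 0.2))),
    list(a, b)), 1e-3)
})

test_that("broadcast add/mul reduce gradients correctly", {
  set.seed(2)
  x <- tp(rnd(4, 5, 3))
  bias <- tp(rnd(1, 1, 3))
  gate <- tp(rnd(4, 5, 1))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_add(p[[1]], p[[2]]), p[[3]])),
    list(x, bias, gate)), 1e-4)
  tok <- tp(rnd(6, 4)); rb <- tp(rnd(4)); cb <- tp(rnd(6, 1))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_add(p[[1]], p[[2]]), p[[3]])),
    list(tok, rb, cb)), 1e-4)
})

test_that("activation gradients match finite differences", {
  set.seed(3)
  x <- tp(rnd(3, 7) * 2)
  for (op in list(ns$t_relu, ns$t_relu6, ns$t_sigmoid, ns$t_hsigmoid,
                  ns$t_silu))
    expect_lt(gradcheck(function(p) ns$t_sum(op(p[[1]])), list(x)), 1e-3)
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_softmax_rows(p[[1]]), kc(3, 7))),
    list(x)), 1e-4)
})

test_that("convolution gradients (stride, dilation, groups, bias, rect) check out", {
  set.seed(4)
  x <- tp(rnd(6, 7, 4))
  w <- tp(ns$init_conv_w(3, 3, 4, 5)); b <- tp(rnorm(5))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_conv2d(p[[1]], p[[2]], p[[3]], stride = 2L, pad = 1L)),
    list(x, w, b)), 1e-4)
  wd <- tp(ns$init_conv_w(3, 3, 1, 4))   # depthwise dilated
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_conv2d(p[[1]], p[[2]], NULL, pad = 2L, dil = 2L,
                         groups = 4L)), list(x, wd)), 1e-4)
  wg <- tp(ns$init_conv_w(1, 1, 2, 6))   # grouped pointwise
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_conv2d(p[[1]], p[[2]], NULL, groups = 2L)),
    list(x, wg)), 1e-4)
  ws <- tp(ns$init_conv_w(1, 5, 2, 4))   # horizontal strip, grouped
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_conv2d_rect(p[[1]], p[[2]], pad_h = 0L, pad_w = 2L,
                              groups = 2L)), list(x, ws)), 1e-4)
})

test_that("pooling, resize and normalization gradients check out", {
  set.seed(5)
  x <- tp(rnd(6, 8, 3))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_avgpool(p[[1]], 2L), kc(3, 4, 3))),
    list(x)), 1e-4)
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_maxpool(p[[1]], 3L, 2L, 1L), kc(3, 4, 3))),
    list(x)), 1e-3)
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_resize_bilinear(p[[1]], 9L, 5L),
                      kc(9, 5, 3))), list(x)), 1e-4)
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_gap(p[[1]]), kc(1, 1, 3))), list(x)), 1e-4)
  g <- tp(runif(3, 0.5, 1.5)); bta <- tp(rnorm(3))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_instnorm(p[[1]], p[[2]], p[[3]]),
                      kc(6, 8, 3))), list(x, g, bta)), 1e-3)
  tokg <- tp(runif(5, 0.5, 1.5)); tokb <- tp(rnorm(5))
  tok <- tp(rnd(7, 5))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_layernorm(p[[1]], p[[2]], p[[3]]),
                      kc(7, 5))), list(tok, tokg, tokb)), 1e-3)
})

test_that("wavelet stack, gather/concat and bilinear sampling gradients check out", {
  set.seed(6)
  x <- tp(rnd(6, 8, 2))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_dwt_haar(p[[1]]), kc(3, 4, 8))),
    list(x)), 1e-4)
  sb <- tp(rnd(3, 4, 8))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_idwt_haar(p[[1]]), kc(6, 8, 2))),
    list(sb)), 1e-4)
  m <- tp(rnd(5, 6, 3))
  co <- tp(cbind(runif(7, 0.2, 4.8), runif(7, 0.2, 3.8)))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_bilinear_sample(p[[1]], p[[2]]),
                      kc(7, 3))), list(m, co)), 1e-3)
  tok <- tp(rnd(6, 4))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_rows_gather(p[[1]], c(2L, 2L, 5L))), list(tok)), 1e-4)
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_cols_idx(p[[1]], c(1L, 3L, 3L)),
                      kc(6, 3))), list(tok)), 1e-4)
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_fold_rows(p[[1]], 3L, 2L), kc(3, 4))),
    list(tok)), 1e-4)
  a3 <- tp(rnd(1, 5, 2)); b3 <- tp(rnd(4, 1, 2))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_broadcast_add_axial(p[[1]], p[[2]]),
                      kc(4, 5, 2))), list(a3, b3)), 1e-4)
  x2 <- tp(rnd(4, 5, 2))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_mean_rows(p[[1]]), kc(1, 5, 2))),
    list(x2)), 1e-4)
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$t_mul(ns$t_mean_cols(p[[1]]), kc(4, 1, 2))),
    list(x2)), 1e-4)
})

test_that("loss primitives have correct gradients", {
  set.seed(7)
  lg <- tp(rnd(5, 2))
  tgt <- matrix(runif(10) > 0.6, 5, 2) * 1
  expect_lt(gradcheck(function(p)
    ns$t_bce_logits(p[[1]], tgt), list(lg)), 1e-4)
  # GIoU loss on boxes kept strictly positive
  raw <- tp(cbind(runif(4, 0.3, 0.7), runif(4, 0.3, 0.7),
                  runif(4, 0.2, 0.4), runif(4, 0.2, 0.4)))
  gt <- cbind(runif(4, 0.3, 0.7), runif(4, 0.3, 0.7),
              runif(4, 0.2, 0.4), runif(4, 0.2, 0.4))
  expect_lt(gradcheck(function(p)
    ns$giou_loss_t(p[[1]], gt), list(raw)), 1e-3)
})

test_that("composite blocks are differentiable end to end", {
  set.seed(8)
  # RCM block
  rcm <- ns$make_rcm(4L, 3L, 2L)
  x <- tp(rnd(4, 6, 4))
  ps <- c(list(x), ns$collect_params(rcm))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$rcm_fwd(rcm, p[[1]])), ps), 1e-3)
  # M2SA block
  m2 <- ns$build_m2sa(m2sa_config(hidden = 8L, heads = 2L, se_r = 4L))
  xm <- tp(rnd(3, 3, 8))
  ps <- c(list(xm), ns$collect_params(m2))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$m2sa_block_fwd(m2, p[[1]])), ps), 1e-3)
  # WTConv layer
  wl <- ns$make_wtconv(2L, 3L, levels = 2L, k = 3L, base_k = 3L)
  xw <- tp(rnd(8, 8, 2))
  ps <- c(list(xw), ns$collect_params(wl))
  expect_lt(gradcheck(function(p)
    ns$t_sum(ns$wtconv_fwd(wl, p[[1]])), ps), 1e-3)
})
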