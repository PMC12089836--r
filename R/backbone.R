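# ResNet18 backbone (7x7 stem + max pool, 1x1 projection shortcuts) with
# optional replacement of BasicBlock 3x3 convolutions by depthwise WTConv +
# 1x1 pointwise mixing. Produces the feature pyramid {P3, P4, P5} at strides
# {8, 16, 32} with widths {128, 256, 512}.

# A replacement policy names which BasicBlock 3x3 convolutions become
# WTConv, at per-convolution granularity: a list of four stages, each a list
# of two blocks, each a logical pair (conv1, conv2). Presets cover the
# shipped configurations.
wt_policy <- function(name) {
  all_on <- function() list(c(TRUE, TRUE), c(TRUE, TRUE))
  all_off <- function() list(c(FALSE, FALSE), c(FALSE, FALSE))
  presets <- list(
    none = list(all_off(), all_off(), all_off(), all_off()),
    full = list(all_on(), all_on(), all_on(), all_on()),
    # default: stages 2-3 and the final stage-4 block, keeping the first
    # high-resolution stage and the stage-2 entry (strided) convolution
    # dense; this is the configuration shipped with the package profile
    balanced = list(all_off(),
                    list(c(FALSE, TRUE), c(TRUE, TRUE)),
                    all_on(),
                    list(c(FALSE, FALSE), c(TRUE, TRUE))),
    deep = list(all_off(), all_off(), all_on(), all_on())
  )
  if (is.list(name)) {
    stopifnot(length(name) == 4L)
    return(name)
  }
  if (!name %in% names(presets))
    stop("unknown WTConv replacement policy '", name, "'; one of: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

# Deepest wavelet level whose smallest decomposed map stays >= 2x2 at the
# given input resolution; 0 means no level fits.
wt_levels_for <- function(res, want) {
  fit <- if (res >= 4L) floor(log2(res / 2)) else 0L
  max(0L, min(want, fit))
}

make_basic_block <- function(cin, cout, stride, wt, wtcfg, res = 640L) {
  lv1 <- wt_levels_for(res, wtcfg$levels)
  lv2 <- wt_levels_for(res %/% stride, wtcfg$levels)
  wt <- c(wt[1] && lv1 > 0L, wt[2] && lv2 > 0L)
  bl <- list(kind = "basic_block", cin = cin, cout = cout, stride = stride,
             wt = wt)
  bl$conv1 <- if (wt[1])
    make_wtconv(cin, cout, stride = stride, levels = lv1,
                k = wtcfg$band_kernel, base_k = wtcfg$base_kernel,
                act = "relu")
  else make_conv(cin, cout, k = 3L, stride = stride, act = "relu")
  bl$conv2 <- if (wt[2])
    make_wtconv(cout, cout, stride = 1L, levels = lv2,
                k = wtcfg$band_kernel, base_k = wtcfg$base_kernel,
                act = "none")
  else make_conv(cout, cout, k = 3L, act = "none")
  if (stride != 1L || cin != cout)
    bl$shortcut <- make_conv(cin, cout, k = 1L, act = "none")
  bl
}

block_fwd <- function(bl, x) {
  y <- if (bl$wt[1]) wtconv_fwd(bl$conv1, x) else conv_fwd(bl$conv1, x)
  y <- if (bl$wt[2]) wtconv_fwd(bl$conv2, y) else conv_fwd(bl$conv2, y)
  sc <- x
  if (!is.null(bl$shortcut)) {
    if (bl$stride != 1L) sc <- t_avgpool(sc, bl$stride)
    sc <- conv_fwd(bl$shortcut, sc)
  }
  t_relu(t_add(y, sc))
}

block_flops <- function(bl, h, w) {
  f1 <- if (bl$wt[1]) wtconv_layer_flops(bl$conv1, h, w)
        else conv_flops(bl$conv1, h, w)
  f2 <- if (bl$wt[2]) wtconv_layer_flops(bl$conv2, f1$h, f1$w)
        else conv_flops(bl$conv2, f1$h, f1$w)
  f <- f1$f + f2$f
  if (!is.null(bl$shortcut))
    f <- f + conv_flops(bl$shortcut, f1$h, f1$w)$f
  list(f = f, h = f2$h, w = f2$w)
}

#' Build the detector backbone
#'
#' ResNet18 topology (7x7 stem + four stages of two BasicBlocks) whose
#' designated 3x3 convolutions are replaced by depthwise wavelet-transform
#' convolution followed by a 1x1 pointwise channel-mixing convolution.
#'
#' @param wt logical: replace convolutions per `policy` (FALSE gives the plain
#'   baseline backbone).
#' @param policy replacement policy preset name (see Details) or a list of
#'   four logical vectors, one flag per BasicBlock.
#' @param wtcfg a [wtconv_config()] describing levels and kernel sizes; the
#'   level count is clamped per layer so the smallest decomposed map stays at
#'   least 2x2 at `input_size` (layers where no level fits stay dense).
#' @param input_size square input size the backbone is built for.
#' @return a backbone module; run it with `backbone_fwd()` to obtain the
#'   feature pyramid `list(P3, P4, P5)` at strides 8/16/32.
#' @details Presets: `"none"` (plain ResNet18), `"full"` (every block),
#'   `"balanced"` (stages 2-3 and the last stage-4 block; the shipped
#'   default), `"deep"` (stages 3-4).
#' @export
build_wt_backbone <- function(wt = TRUE, policy = "balanced",
                              wtcfg = wtconv_config(), input_size = 640L) {
  pol <- wt_policy(policy)
  if (!wt) pol <- wt_policy("none")
  widths <- c(64L, 128L, 256L, 512L)
  bb <- list(kind = "backbone",
             stem = list(make_conv(3L, 64L, k = 7L, stride = 2L,
                                   act = "relu")))
  stages <- vector("list", 4L)
  cin <- 64L
  res <- input_size %/% 4L       # resolution entering stage 1
  for (s in seq_len(4L)) {
    cout <- widths[s]
    stride <- if (s == 1L) 1L else 2L
    stages[[s]] <- list(
      make_basic_block(cin, cout, stride, pol[[s]][[1]], wtcfg, res),
      make_basic_block(cout, cout, 1L, pol[[s]][[2]], wtcfg, res %/% stride))
    cin <- cout
    res <- res %/% stride
  }
  bb$stages <- stages
  bb
}

backbone_fwd <- function(bb, x) {
  for (l in bb$stem) x <- conv_fwd(l, x)
  x <- t_maxpool(x, 3L, 2L, 1L)
  outs <- vector("list", 4L)
  for (s in seq_len(4L)) {
    for (bl in bb$stages[[s]]) x <- block_fwd(bl, x)
    outs[[s]] <- x
  }
  list(P3 = outs[[2L]], P4 = outs[[3L]], P5 = outs[[4L]])
}

backbone_flops <- function(bb, h, w) {
  f <- 0
  for (l in bb$stem) {
    r <- conv_flops(l, h, w); f <- f + r$f; h <- r$h; w <- r$w
  }
  h <- conv_out_size(h, 3L, 2L, 1L)   # max pool (not FLOP-counted)
  w <- conv_out_size(w, 3L, 2L, 1L)
  sizes <- list()
  for (s in seq_len(4L)) {
    for (bl in bb$stages[[s]]) {
      r <- block_flops(bl, h, w); f <- f + r$f; h <- r$h; w <- r$w
    }
    sizes[[s]] <- c(h, w)
  }
  list(f = f, sizes = sizes)
}
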