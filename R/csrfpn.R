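# Context-guided spatial feature reconstruction neck (CSRFPN): rectangular
# self-calibration (RCM), pyramid context extraction (PCE), dynamic
# interpolation fusion (DIF) and multi-feature fusion (MFF), wired as
#   context = PCE(P3, P4, P5)
#   N5 = RCM(DIF(P5, context));  N4 = RCM(MFF(P4, N5));  N3 = RCM(MFF(P3, N4))

# axial pooling ops ----------------------------------------------------------

t_mean_rows <- function(x) {          # (H, W, C) -> (1, W, C)
  x <- as_wt(x); d <- dim(x$v)
  v <- colMeans(x$v, dims = 1L)       # (W, C)
  new_node(array(v, c(1L, d[2], d[3])), list(x), function(g)
    list(array(rep(as.vector(g) / d[1], each = d[1]), d)))
}

t_mean_cols <- function(x) {          # (H, W, C) -> (H, 1, C)
  x <- as_wt(x); d <- dim(x$v)
  v <- colMeans(aperm(x$v, c(2L, 1L, 3L)), dims = 1L)  # (H, C)
  new_node(array(v, c(d[1], 1L, d[3])), list(x), function(g) {
    gm <- array(as.vector(g), c(d[1], d[3])) / d[2]
    list(aperm(array(rep(as.vector(aperm(array(gm, c(d[1], 1L, d[3])),
                                         c(2L, 1L, 3L))), each = d[2]),
                     c(d[2], d[1], d[3])), c(2L, 1L, 3L)))
  })
}

t_broadcast_add_axial <- function(a, b) {  # (1,W,C) + (H,1,C) -> (H,W,C)
  a <- as_wt(a); b <- as_wt(b)
  da <- dim(a$v); db <- dim(b$v)
  H <- db[1]; W <- da[2]; C <- da[3]
  av <- array(rep(as.vector(a$v), each = H), c(H, W, C))
  bv <- array(apply(b$v, 3L, function(m) matrix(m, H, W)), c(H, W, C))
  new_node(av + bv, list(a, b), function(g)
    list(array(colSums(g, dims = 1L), da),
         array(as.vector(colMeans(aperm(g, c(2L, 1L, 3L)), dims = 1L)) * W,
               db)))
}

#' Neck configuration
#'
#' @param hidden common hidden width C.
#' @param strip_k odd kernel size of the RCM strip convolutions.
#' @param pce_depth number of stacked RCMs applied to the pooled context.
#' @param pce_strip_groups channel groups of the strip convolutions inside the
#'   context RCMs (1 = full channel mixing; `hidden` = depthwise).
#' @param level_strip_groups same, for the per-level RCMs.
#' @param mff_main_k,mff_main_groups kernel / groups of the MFF convolution on
#'   the high-resolution input.
#' @param mff_gate_k,mff_gate_groups kernel / groups of the MFF gate
#'   convolution on the low-resolution input.
#' @return a `neck_config` list.
#' @export
neck_config <- function(hidden = 256L, strip_k = 9L, pce_depth = 2L,
                        pce_strip_groups = 2L, level_strip_groups = hidden,
                        mff_main_k = 3L, mff_main_groups = 2L,
                        mff_gate_k = 3L, mff_gate_groups = 1L) {
  if (strip_k %% 2L == 0L) stop("strip kernel must be odd")
  structure(list(hidden = as.integer(hidden), strip_k = as.integer(strip_k),
                 pce_depth = as.integer(pce_depth),
                 pce_strip_groups = as.integer(pce_strip_groups),
                 level_strip_groups = as.integer(level_strip_groups),
                 mff_main_k = as.integer(mff_main_k),
                 mff_main_groups = as.integer(mff_main_groups),
                 mff_gate_k = as.integer(mff_gate_k),
                 mff_gate_groups = as.integer(mff_gate_groups)),
            class = "neck_config")
}

# --- RCM --------------------------------------------------------------------

make_rcm <- function(C, k = 11L, strip_groups = C) {
  if (k %% 2L == 0L) stop("strip kernel must be odd")
  list(kind = "rcm", C = C, k = k,
       strip_h = make_conv_strip(C, k, horizontal = TRUE, groups = strip_groups),
       strip_v = make_conv_strip(C, k, horizontal = FALSE, groups = strip_groups),
       dw = make_conv(C, C, k = 3L, groups = C, norm = FALSE, bias = TRUE))
}

# 1 x k (horizontal) or k x 1 (vertical) strip convolution
make_conv_strip <- function(C, k, horizontal, groups) {
  kh <- if (horizontal) 1L else k
  kw <- if (horizontal) k else 1L
  l <- list(kind = "strip", C = C, kh = kh, kw = kw, groups = groups,
            w = tp(init_conv_w(kh, kw, C %/% groups, C)),
            gamma = tp(rep(1, C)), beta = tp(numeric(C)))
  l
}

strip_fwd <- function(l, x, norm_relu = FALSE) {
  y <- t_conv2d_rect(x, l$w, stride = 1L,
                     pad_h = (l$kh - 1L) %/% 2L, pad_w = (l$kw - 1L) %/% 2L,
                     groups = l$groups)
  if (norm_relu) y <- t_relu(t_instnorm(y, l$gamma, l$beta))
  y
}

# rectangular-kernel convolution built on the square-kernel primitive by
# padding asymmetrically through the generic pad arguments
t_conv2d_rect <- function(x, w, stride = 1L, pad_h = 0L, pad_w = 0L,
                          groups = 1L) {
  x <- as_wt(x); w <- as_wt(w)
  dx <- dim(x$v); dw <- dim(w$v)
  keep <- (w$req || x$req) &&
    (dw[1] * dw[2] * (dx[3] / groups) * dx[1] * dx[2] * groups) <= 2^18
  r0 <- conv2d_fw_cpp(x$v, w$v, NULL, dx[1], dx[2], dx[3], dw[1], dw[2],
                      dw[4], stride, pad_h, pad_w, 1L, groups, keep)
  v <- r0$out
  col <- if (keep) r0$col else NULL
  if (!is.null(.wmc$flops)) {
    dv <- dim(v)
    .wmc$flops <- .wmc$flops +
      2 * dw[1] * dw[2] * (dx[3] / groups) * dw[4] * dv[1] * dv[2]
  }
  new_node(v, list(x, w), function(g) {
    r <- conv2d_bw_cpp(x$v, w$v, g, dx[1], dx[2], dx[3], dw[1], dw[2],
                       dw[4], stride, pad_h, pad_w, 1L, groups, x$req, FALSE,
                       col)
    gw <- r$gw; dim(gw) <- dw
    list(if (x$req) r$gx else NULL, gw)
  })
}

strip_flops <- function(l, h, w)
  2 * l$kh * l$kw * (l$C / l$groups) * l$C * h * w

rcm_fwd <- function(l, x) {
  hp <- t_mean_rows(x)                       # (1, W, C)
  vp <- t_mean_cols(x)                       # (H, 1, C)
  y <- t_broadcast_add_axial(hp, vp)         # rectangular attention region
  y <- strip_fwd(l$strip_h, y, norm_relu = TRUE)
  y <- t_sigmoid(strip_fwd(l$strip_v, y))
  t_mul(conv_fwd(l$dw, x), y)
}

rcm_flops <- function(l, h, w) {
  strip_flops(l$strip_h, h, w) + strip_flops(l$strip_v, h, w) +
    conv_flops(l$dw, h, w)$f
}

#' Rectangular self-calibration of a feature map
#'
#' Axial (row and column) average pooling broadcast into a rectangular
#' attention region, refined by two large-kernel strip convolutions and a
#' sigmoid, then multiplied into a depthwise 3x3 transform of the input.
#'
#' @param m a module from [build_csrfpn()] component list, or built directly
#'   with the internal constructor via [build_csrfpn()].
#' @param x numeric (H, W, C) array.
#' @return numeric (H, W, C) array.
#' @export
rcm <- function(m, x) val(rcm_fwd(m, tt(check_map(x))))

# --- PCE --------------------------------------------------------------------

make_pce <- function(cfg) {
  C <- cfg$hidden
  list(kind = "pce", cfg = cfg,
       fuse = make_conv(3L * C, C, k = 1L, act = "none"),
       rcms = lapply(seq_len(cfg$pce_depth), function(i)
         make_rcm(C, cfg$strip_k, cfg$pce_strip_groups)))
}

pce_fwd <- function(l, p3, p4, p5) {
  for (nm in c("p3", "p4", "p5")) {
    d <- dim(val(get(nm)))
    fac <- c(p3 = 8L, p4 = 4L, p5 = 2L)[[nm]]
    if (d[1] %% fac != 0L || d[2] %% fac != 0L)
      stop("level ", toupper(nm), " size ", d[1], "x", d[2],
           " not divisible by its pooling factor ", fac)
  }
  pooled <- list(t_avgpool(p3, 8L), t_avgpool(p4, 4L), t_avgpool(p5, 2L))
  y <- conv_fwd(l$fuse, t_concat_c(pooled))
  for (r in l$rcms) y <- rcm_fwd(r, y)
  y
}

pce_flops <- function(l, h3, w3) {
  h <- h3 %/% 8L; w <- w3 %/% 8L
  f <- conv_flops(l$fuse, h, w)$f
  for (r in l$rcms) f <- f + rcm_flops(r, h, w)
  f
}

#' Pyramid context extraction
#'
#' Pools the three pyramid levels to a shared coarse grid (factors 8/4/2),
#' fuses them with a 1x1 convolution and refines with stacked RCMs.
#'
#' @param m a PCE module (component `pce` of [build_csrfpn()]).
#' @param p3,p4,p5 numeric arrays at strides 8/16/32 of a common image size
#'   divisible by 64, all at the hidden width.
#' @return context map at the common pooled grid.
#' @export
pce <- function(m, p3, p4, p5)
  val(pce_fwd(m, tt(check_map(p3)), tt(check_map(p4)), tt(check_map(p5))))

# --- DIF / MFF --------------------------------------------------------------

make_dif <- function(c0, c1) {
  list(kind = "dif", proj = make_conv(c1, c0, k = 1L, act = "none"))
}

dif_fwd <- function(l, x0, x1) {
  d <- dim(val(x0))
  t_add(x0, conv_fwd(l$proj, t_resize_bilinear(x1, d[1], d[2])))
}

dif_flops <- function(l, h0, w0) conv_flops(l$proj, h0, w0)$f

#' Dynamic interpolation fusion
#'
#' Bilinearly resizes `x1` to the grid of `x0`, aligns channels with a 1x1
#' convolution, and adds elementwise.
#'
#' @param m a DIF module (from [build_csrfpn()]).
#' @param x0 target-resolution map; `x1` map to be fused into it.
#' @return array shaped like `x0`.
#' @export
dif <- function(m, x0, x1) val(dif_fwd(m, tt(check_map(x0)), tt(check_map(x1))))

make_mff <- function(cfg, ch, cl) {
  C <- cfg$hidden
  list(kind = "mff",
       main = make_conv(ch, C, k = cfg$mff_main_k,
                        groups = cfg$mff_main_groups, act = "none"),
       gate = make_conv(cl, C, k = cfg$mff_gate_k,
                        groups = cfg$mff_gate_groups, act = "none"))
}

mff_fwd <- function(l, xh, xl) {
  d <- dim(val(xh))
  g <- t_hsigmoid(conv_fwd(l$gate, xl))
  g <- t_resize_bilinear(g, d[1], d[2])
  t_mul(g, conv_fwd(l$main, xh))
}

mff_flops <- function(l, hh, wh, hl, wl)
  conv_flops(l$main, hh, wh)$f + conv_flops(l$gate, hl, wl)$f

#' Multi-feature fusion
#'
#' A hard-sigmoid gate computed from the low-resolution map, bilinearly
#' upsampled and multiplied into a convolution of the high-resolution map.
#'
#' @param m an MFF module (from [build_csrfpn()]).
#' @param xh high-resolution map; `xl` low-resolution map.
#' @return array at `xh`'s resolution.
#' @export
mff <- function(m, xh, xl) val(mff_fwd(m, tt(check_map(xh)), tt(check_map(xl))))

# --- the neck ---------------------------------------------------------------

#' Build the CSRFPN neck
#'
#' Maps the projected pyramid `{P3, P4, P5}` (P5 already passed through the
#' encoder layer) to decoder inputs `{N3, N4, N5}` at strides 8/16/32 and the
#' common hidden width: the pooled context enters at P5 through DIF, then a
#' top-down MFF cascade with an RCM at every level.
#'
#' @param cfg a [neck_config()].
#' @return a neck module; run with [csrfpn_forward()].
#' @export
build_csrfpn <- function(cfg = neck_config()) {
  C <- cfg$hidden
  list(kind = "csrfpn", cfg = cfg,
       pce = make_pce(cfg),
       dif5 = make_dif(C, C),
       mff4 = make_mff(cfg, C, C),
       mff3 = make_mff(cfg, C, C),
       rcm5 = make_rcm(C, cfg$strip_k, cfg$level_strip_groups),
       rcm4 = make_rcm(C, cfg$strip_k, cfg$level_strip_groups),
       rcm3 = make_rcm(C, cfg$strip_k, cfg$level_strip_groups))
}

csrfpn_fwd <- function(l, p3, p4, p5) {
  ctx <- pce_fwd(l$pce, p3, p4, p5)
  n5 <- rcm_fwd(l$rcm5, dif_fwd(l$dif5, p5, ctx))
  n4 <- rcm_fwd(l$rcm4, mff_fwd(l$mff4, p4, n5))
  n3 <- rcm_fwd(l$rcm3, mff_fwd(l$mff3, p3, n4))
  list(N3 = n3, N4 = n4, N5 = n5)
}

csrfpn_flops <- function(l, h3, w3) {
  h4 <- h3 %/% 2L; w4 <- w3 %/% 2L
  h5 <- h3 %/% 4L; w5 <- w3 %/% 4L
  pce_flops(l$pce, h3, w3) +
    dif_flops(l$dif5, h5, w5) + rcm_flops(l$rcm5, h5, w5) +
    mff_flops(l$mff4, h4, w4, h5, w5) + rcm_flops(l$rcm4, h4, w4) +
    mff_flops(l$mff3, h3, w3, h4, w4) + rcm_flops(l$rcm3, h3, w3)
}

#' @rdname build_csrfpn
#' @param neck a module from [build_csrfpn()].
#' @param p3,p4,p5 numeric arrays at strides 8/16/32, hidden width.
#' @export
csrfpn_forward <- function(neck, p3, p4, p5) {
  out <- csrfpn_fwd(neck, tt(check_map(p3)), tt(check_map(p4)),
                    tt(check_map(p5)))
  lapply(out, val)
}
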