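# Haar wavelet machinery: orthonormal 2-D DWT/IDWT, the wavelet-transform
# convolution operator (WTConv), and the closed-form FLOP calculators for its
# decomposition / per-band convolution / reconstruction stages.

check_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L || any(dim(x) == 0L))
    stop("expected a non-empty (H, W, C) array")
  x
}

reflect_pad_even <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L == 1L) x <- x[c(seq_len(d[1]), d[1] - 1L), , , drop = FALSE]
  d <- dim(x)
  if (d[2] %% 2L == 1L) x <- x[, c(seq_len(d[2]), d[2] - 1L), , drop = FALSE]
  x
}

#' Orthonormal 2-D Haar wavelet decomposition
#'
#' Splits a feature map into one low-pass (`LL`) and three detail subbands at
#' half resolution. Every output coefficient is a +/- 1/2-weighted sum of a
#' 2x2 input block, so the transform is orthonormal: energy is conserved and
#' [haar_idwt2()] inverts it exactly. `LH` carries horizontal (column
#' difference) detail, `HL` vertical (row difference) detail and `HH`
#' diagonal detail.
#'
#' Odd spatial sizes are reflect-padded (right/bottom) to even before the
#' transform.
#'
#' @param x numeric matrix (H, W) or array (H, W, C).
#' @return list with subband arrays `LL`, `LH`, `HL`, `HH`, each
#'   (ceil(H/2), ceil(W/2), C).
#' @examples
#' s <- haar_dwt2(matrix(c(1, 3, 2, 4), 2, 2))  # LL = 5
#' @export
haar_dwt2 <- function(x) {
  x <- reflect_pad_even(check_map(x))
  sb <- haar_analysis(x)
  C <- dim(x)[3]
  list(LL = sb[, , seq_len(C), drop = FALSE],
       LH = sb[, , C + seq_len(C), drop = FALSE],
       HL = sb[, , 2L * C + seq_len(C), drop = FALSE],
       HH = sb[, , 3L * C + seq_len(C), drop = FALSE])
}

#' Inverse orthonormal 2-D Haar transform
#'
#' Exact inverse (transpose) of [haar_dwt2()] for even-sized inputs.
#'
#' @param subbands list with arrays `LL`, `LH`, `HL`, `HH` of identical shape.
#' @return array (2H, 2W, C).
#' @export
haar_idwt2 <- function(subbands) {
  sb <- lapply(subbands[c("LL", "LH", "HL", "HH")], check_map)
  d <- dim(sb$LL)
  if (!all(vapply(sb, function(b) identical(dim(b), d), logical(1))))
    stop("subband shapes must match")
  haar_synthesis(array(unlist(sb, use.names = FALSE), c(d[1], d[2], 4L * d[3])))
}

#' WTConv configuration
#'
#' @param levels number of wavelet decomposition levels (>= 1).
#' @param band_kernel odd kernel size of the per-subband depthwise
#'   convolutions.
#' @param channels number of channels the operator acts on (depthwise).
#' @param base_kernel odd kernel size of the full-resolution depthwise base
#'   convolution.
#' @return a `wtconv_config` list.
#' @export
wtconv_config <- function(levels = 2L, band_kernel = 3L, channels = 1L,
                          base_kernel = 5L) {
  if (levels < 1L) stop("levels must be >= 1")
  if (band_kernel %% 2L == 0L || base_kernel %% 2L == 0L)
    stop("kernels must be odd")
  structure(list(levels = as.integer(levels),
                 band_kernel = as.integer(band_kernel),
                 channels = as.integer(channels),
                 base_kernel = as.integer(base_kernel)),
            class = "wtconv_config")
}

check_wt_levels <- function(H, W, levels) {
  for (i in seq_len(levels)) {
    H <- ceiling(H / 2); W <- ceiling(W / 2)
    if (H < 2 || W < 2)
      stop("wavelet level ", i, " would produce a ", H, "x", W,
           " map; reduce `levels` for this input size")
  }
  invisible(TRUE)
}

# Forward pass of the WTConv core on a wt tensor (depthwise; channel count
# preserved). Decomposition recurses on the *unconvolved* LL band; the
# convolved LL bands are summed into the IWT cascade on the way back up.
wtconv_core_fwd <- function(x, base_w, band_ws, levels, k, base_k) {
  d <- dim(val(x)); C <- d[3]
  check_wt_levels(d[1], d[2], levels)
  base <- t_conv2d(x, base_w, stride = 1L, pad = (base_k - 1L) %/% 2L,
                   groups = C)
  rec <- function(cur, i) {
    dcur <- dim(val(cur))
    padded <- dcur[1] %% 2L == 1L || dcur[2] %% 2L == 1L
    if (padded) cur <- t_pad_reflect_even(cur)
    sb <- t_dwt_haar(cur)
    conv <- t_conv2d(sb, band_ws[[i]], stride = 1L, pad = (k - 1L) %/% 2L,
                     groups = 4L * C)
    if (i < levels) {
      ll_next <- t_cols3(sb, 1L, C)
      deeper <- rec(ll_next, i + 1L)
      ll_sum <- t_add(t_cols3(conv, 1L, C), deeper)
      conv <- t_concat_c(list(ll_sum, t_cols3(conv, C + 1L, 4L * C)))
    }
    out <- t_idwt_haar(conv)
    if (padded) out <- t_crop_hw(out, dcur[1], dcur[2])
    out
  }
  t_add(base, rec(x, 1L))
}

# channel slice of a 3-D tensor
t_cols3 <- function(x, from, to) {
  x <- as_wt(x); d <- dim(x$v)
  new_node(x$v[, , from:to, drop = FALSE], list(x), function(g) {
    gx <- array(0, d); gx[, , from:to] <- g; list(gx)
  })
}

t_crop_hw <- function(x, h, w) {
  x <- as_wt(x); d <- dim(x$v)
  if (d[1] == h && d[2] == w) return(x)
  new_node(x$v[seq_len(h), seq_len(w), , drop = FALSE], list(x), function(g) {
    gx <- array(0, d); gx[seq_len(h), seq_len(w), ] <- g; list(gx)
  })
}

t_pad_reflect_even <- function(x) {
  x <- as_wt(x); d <- dim(x$v)
  ph <- d[1] %% 2L; pw <- d[2] %% 2L
  ri <- c(seq_len(d[1]), if (ph) d[1] - 1L)
  ci <- c(seq_len(d[2]), if (pw) d[2] - 1L)
  new_node(x$v[ri, ci, , drop = FALSE], list(x), function(g) {
    gx <- g[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
    if (ph) gx[d[1] - 1L, , ] <- gx[d[1] - 1L, , ] + g[d[1] + 1L, seq_len(d[2]), ]
    if (pw) gx[, d[2] - 1L, ] <- gx[, d[2] - 1L, ] + g[seq_len(d[1]), d[2] + 1L, ]
    if (ph && pw)
      gx[d[1] - 1L, d[2] - 1L, ] <- gx[d[1] - 1L, d[2] - 1L, ] +
        g[d[1] + 1L, d[2] + 1L, ]
    list(gx)
  })
}

#' Wavelet-transform convolution of a feature map
#'
#' Decomposes the input with a cascaded orthonormal Haar transform, applies a
#' small depthwise convolution to every subband at every level, reconstructs
#' with the inverse transform, and adds a full-resolution depthwise base
#' convolution. Spatial size and channel count are preserved. This is the
#' depthwise operator; inside the backbone it is followed by a 1x1 pointwise
#' channel-mixing convolution.
#'
#' @param x numeric (H, W, C) array (a matrix is treated as C = 1).
#' @param cfg a [wtconv_config()].
#' @param weights list with `base` - (base_kernel, base_kernel, 1, C) array -
#'   and `bands` - list of `levels` arrays (band_kernel, band_kernel, 1, 4C),
#'   subband channel order LL, LH, HL, HH.
#' @return numeric (H, W, C) array.
#' @export
wtconv2d <- function(x, cfg, weights) {
  x <- check_map(x)
  C <- dim(x)[3]
  stopifnot(inherits(cfg, "wtconv_config"))
  if (length(weights$bands) != cfg$levels)
    stop("need one band-kernel array per level")
  out <- wtconv_core_fwd(tt(x), tt(weights$base), lapply(weights$bands, tt),
                         cfg$levels, cfg$band_kernel, cfg$base_kernel)
  val(out)
}

check_flop_args <- function(...) {
  a <- c(...)
  if (any(a <= 0)) stop("all arguments must be positive")
  invisible(TRUE)
}

#' Closed-form FLOP counts of the WTConv stages
#'
#' `flops_wt()` counts the cascaded wavelet decomposition of a C_in-channel
#' H x W map over `levels` levels; `flops_iwt()` is its mirror image for the
#' reconstruction; `flops_bands()` counts the per-band convolutions with a
#' k x k kernel. `flops_bands()` is written with the full C_in x C_out
#' product, matching the closed form these counts are defined by; the shipped
#' operator itself is depthwise + pointwise, and the model profiler counts
#' that actual depthwise cost.
#'
#' @param C_in,C_out channel counts.
#' @param H,W spatial size of the map entering the operator.
#' @param k band kernel size.
#' @param levels number of decomposition levels (>= 1).
#' @return FLOP count (numeric scalar).
#' @export
flops_wt <- function(C_in, H, W, levels) {
  check_flop_args(C_in, H, W, levels)
  C_in * sum(4 * H * W / 2^(0:(levels - 1)))
}

#' @rdname flops_wt
#' @export
flops_bands <- function(C_in, C_out, H, W, k, levels) {
  check_flop_args(C_in, C_out, H, W, k, levels)
  sum((H * W / 2^(1:levels)) * k^2 * 4 * C_in * C_out)
}

#' @rdname flops_wt
#' @export
flops_iwt <- function(C_out, H, W, levels) {
  check_flop_args(C_out, H, W, levels)
  C_out * sum(4 * H * W / 2^(0:(levels - 1)))
}

# --- WTConv as a network layer ----------------------------------------------

# Depthwise WTConv core + 1x1 pointwise mixing (+ channel norm). `stride` is
# applied by the pointwise convolution.
make_wtconv <- function(cin, cout, stride = 1L, levels = 2L, k = 3L,
                        base_k = 5L, act = "none") {
  list(kind = "wtconv", cin = cin, cout = cout, stride = stride,
       levels = levels, k = k, base_k = base_k,
       base_w = tp(init_conv_w(base_k, base_k, 1L, cin)),
       band_ws = lapply(seq_len(levels), function(i)
         tp(init_conv_w(k, k, 1L, 4L * cin))),
       pw = make_conv(cin, cout, k = 1L, stride = stride, norm = TRUE,
                      act = act))
}

wtconv_fwd <- function(l, x) {
  y <- wtconv_core_fwd(x, l$base_w, l$band_ws, l$levels, l$k, l$base_k)
  conv_fwd(l$pw, y)
}

# Analytic FLOPs of the layer: depthwise base + depthwise band convolutions
# at their true (quartered-area) sizes, the closed-form WT/IWT cost, and the
# pointwise mix.
wtconv_layer_flops <- function(l, h, w) {
  f <- 2 * l$base_k^2 * l$cin * h * w                 # base depthwise
  for (i in seq_len(l$levels))
    f <- f + 2 * l$k^2 * 4 * l$cin * (h * w / 4^i)    # subband depthwise
  f <- f + flops_wt(l$cin, h, w, l$levels) + flops_iwt(l$cin, h, w, l$levels)
  pwf <- conv_flops(l$pw, h, w)
  list(f = f + pwf$f, h = pwf$h, w = pwf$w)
}
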