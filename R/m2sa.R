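# Multiscale multihead self-attention (M2SA): a dilated-convolution gating
# branch, a scaled dot-product attention branch (queries from the input,
# keys/values from the multi-scale features) and a squeeze-excitation channel
# attention branch, summed; and M2SA-AIFI, the encoder layer applied to the
# top pyramid level.

#' M2SA configuration
#'
#' @param hidden hidden width C (divisible by `heads`, by 4 and by `se_r`).
#' @param heads number of attention heads.
#' @param rates dilation rates of the three parallel depthwise 3x3 branches.
#' @param se_r squeeze-excitation channel reduction.
#' @param kv_ratio spatial downsampling ratio applied to the multi-scale
#'   features before they form keys/values (1 = none).
#' @param literal_eq6 if TRUE, gate the input twice (see the methods
#'   vignette); default is a single gating.
#' @return an `m2sa_config` list.
#' @export
m2sa_config <- function(hidden = 256L, heads = 8L, rates = c(1L, 3L, 5L),
                        se_r = 16L, kv_ratio = 1L, literal_eq6 = FALSE) {
  if (hidden %% heads != 0L) stop("hidden width must be divisible by heads")
  if (hidden %% 4L != 0L) stop("hidden width must be divisible by 4")
  if (hidden %% se_r != 0L) stop("hidden width must be divisible by se_r")
  structure(list(hidden = as.integer(hidden), heads = as.integer(heads),
                 rates = as.integer(rates), se_r = as.integer(se_r),
                 kv_ratio = as.integer(kv_ratio),
                 literal_eq6 = isTRUE(literal_eq6)),
            class = "m2sa_config")
}

#' Build an M2SA block
#'
#' @param cfg an [m2sa_config()].
#' @return an M2SA module usable with [m2sa_forward()] and the branch
#'   functions [m2sa_multiscale()], [m2sa_attention()], [m2sa_channel()].
#' @export
build_m2sa <- function(cfg = m2sa_config()) {
  C <- cfg$hidden; Cr <- C %/% 4L
  list(kind = "m2sa", cfg = cfg,
       ms_reduce = make_conv(C, Cr, k = 1L, norm = FALSE, bias = TRUE),
       ms_dw = lapply(cfg$rates, function(r)
         make_conv(Cr, Cr, k = 3L, dil = r, groups = Cr, norm = FALSE,
                   bias = TRUE)),
       ms_restore = make_conv(Cr, C, k = 1L, norm = FALSE, bias = TRUE),
       attn = make_mha(C, cfg$heads),
       se1 = make_conv(C, C %/% cfg$se_r, k = 1L, norm = FALSE, bias = TRUE),
       se2 = make_conv(C %/% cfg$se_r, C, k = 1L, norm = FALSE, bias = TRUE))
}

ms_branch_fwd <- function(m, x) {
  r <- conv_fwd(m$ms_reduce, x)
  acc <- NULL
  for (dw in m$ms_dw) {
    y <- conv_fwd(dw, r)
    acc <- if (is.null(acc)) y else t_add(acc, y)
  }
  gate <- conv_fwd(m$ms_restore, acc)
  out <- t_mul(gate, x)
  if (m$cfg$literal_eq6) out <- t_mul(out, x)
  out
}

attn_branch_fwd <- function(m, x, x_msa, pos = NULL) {
  d <- dim(val(x))
  q_in <- t_flatten_tokens(x)
  kv_map <- x_msa
  if (m$cfg$kv_ratio > 1L) kv_map <- t_avgpool(kv_map, m$cfg$kv_ratio)
  dk <- dim(val(kv_map))
  kv <- t_flatten_tokens(kv_map)
  if (!is.null(pos)) {
    q_in <- t_add(q_in, pos)
    kpos <- if (identical(dk[1:2], d[1:2])) pos
            else sine_pos_embed_2d(dk[1], dk[2], m$cfg$hidden)
    # add position only to the tokens entering Q and K: route K through an
    # explicitly positioned copy, leave V positionless
    dh <- m$cfg$hidden %/% m$cfg$heads
    qm <- linear_fwd(m$attn$wq, q_in)
    km <- linear_fwd(m$attn$wk, t_add(kv, kpos))
    vm <- linear_fwd(m$attn$wv, kv)
    outs <- vector("list", m$cfg$heads)
    for (h in seq_len(m$cfg$heads)) {
      a <- ((h - 1L) * dh + 1L); b <- h * dh
      lg <- t_scale(t_matmul(t_cols(qm, a, b), t_transpose(t_cols(km, a, b))),
                    1 / sqrt(dh))
      outs[[h]] <- t_matmul(t_softmax_rows(lg), t_cols(vm, a, b))
    }
    out <- linear_fwd(m$attn$wo, t_cols_concat(outs))
  } else {
    out <- mha_fwd(m$attn, q_in, kv)
  }
  t_unflatten_tokens(out, d[1], d[2])
}

se_branch_fwd <- function(m, x) {
  p <- t_gap(x)
  w <- t_sigmoid(conv_fwd(m$se2, t_relu6(conv_fwd(m$se1, p))))
  t_mul(x, w)
}

m2sa_block_fwd <- function(m, x, pos = NULL) {
  xm <- ms_branch_fwd(m, x)
  at <- attn_branch_fwd(m, x, xm, pos)
  ca <- se_branch_fwd(m, x)
  t_add(t_add(xm, at), ca)
}

m2sa_flops <- function(m, h, w) {
  C <- m$cfg$hidden; Cr <- C %/% 4L
  f <- conv_flops(m$ms_reduce, h, w)$f +
    sum(vapply(m$ms_dw, function(l) conv_flops(l, h, w)$f, 0)) +
    conv_flops(m$ms_restore, h, w)$f
  lk <- (h %/% m$cfg$kv_ratio) * (w %/% m$cfg$kv_ratio)
  f <- f + mha_flops(m$attn, h * w, lk)
  f + conv_flops(m$se1, 1L, 1L)$f + conv_flops(m$se2, 1L, 1L)$f
}

#' Run one M2SA branch or the fused block on a feature map
#'
#' `m2sa_multiscale()` computes the dilated-convolution gating branch,
#' `m2sa_attention()` the attention branch (queries from `x`, keys/values
#' from `x_msa`), `m2sa_channel()` the squeeze-excitation branch, and
#' `m2sa_forward()` their elementwise sum. All preserve the (H, W, C) shape.
#'
#' @param m a module from [build_m2sa()].
#' @param x numeric (H, W, C) array with C equal to the configured hidden
#'   width.
#' @param x_msa multi-scale feature map (same shape as `x`).
#' @return numeric (H, W, C) array.
#' @export
m2sa_multiscale <- function(m, x) val(ms_branch_fwd(m, tt(check_map(x))))

#' @rdname m2sa_multiscale
#' @export
m2sa_attention <- function(m, x, x_msa)
  val(attn_branch_fwd(m, tt(check_map(x)), tt(check_map(x_msa))))

#' @rdname m2sa_multiscale
#' @export
m2sa_channel <- function(m, x) val(se_branch_fwd(m, tt(check_map(x))))

#' @rdname m2sa_multiscale
#' @export
m2sa_forward <- function(m, x) val(m2sa_block_fwd(m, tt(check_map(x))))

# --- AIFI encoder layer -----------------------------------------------------

# Transformer encoder layer on the stride-32 level: attention sublayer
# (standard MHA for the baseline, M2SA when cfg$m2sa) with 2-D sine-cosine
# position added to Q/K, then FFN; post-norm residuals.
make_aifi <- function(hidden = 256L, heads = 8L, ffn = 1024L,
                      m2sa = FALSE, m2sa_cfg = NULL) {
  l <- list(kind = "aifi", hidden = hidden, heads = heads, ffn_dim = ffn,
            m2sa = m2sa,
            ln1 = make_layernorm(hidden), ln2 = make_layernorm(hidden),
            ffn1 = make_linear(hidden, ffn), ffn2 = make_linear(ffn, hidden))
  if (m2sa) {
    if (is.null(m2sa_cfg)) m2sa_cfg <- m2sa_config(hidden = hidden,
                                                   heads = heads)
    l$block <- build_m2sa(m2sa_cfg)
  } else {
    l$block <- make_mha(hidden, heads)
  }
  l
}

aifi_fwd <- function(l, x, level = "P5") {
  if (!identical(level, "P5"))
    stop("the intra-scale interaction layer applies to the top (P5) level only")
  d <- dim(val(x))
  pos <- sine_pos_embed_2d(d[1], d[2], l$hidden)
  if (l$m2sa) {
    att <- t_flatten_tokens(m2sa_block_fwd(l$block, x, pos))
  } else {
    tok <- t_flatten_tokens(x)
    qk <- t_add(tok, pos)
    att <- mha_fwd_qk(l$block, qk, qk, tok)
  }
  tok <- t_flatten_tokens(x)
  s <- layernorm_fwd(l$ln1, t_add(tok, att))
  f <- linear_fwd(l$ffn2, t_relu(linear_fwd(l$ffn1, s)))
  s <- layernorm_fwd(l$ln2, t_add(s, f))
  t_unflatten_tokens(s, d[1], d[2])
}

# MHA where Q/K inputs differ from the V input (position-augmented tokens).
mha_fwd_qk <- function(l, q_in, k_in, v_in) {
  dh <- l$d %/% l$heads
  q <- linear_fwd(l$wq, q_in)
  k <- linear_fwd(l$wk, k_in)
  v <- linear_fwd(l$wv, v_in)
  outs <- vector("list", l$heads)
  for (h in seq_len(l$heads)) {
    a <- ((h - 1L) * dh + 1L); b <- h * dh
    lg <- t_scale(t_matmul(t_cols(q, a, b), t_transpose(t_cols(k, a, b))),
                  1 / sqrt(dh))
    outs[[h]] <- t_matmul(t_softmax_rows(lg), t_cols(v, a, b))
  }
  linear_fwd(l$wo, t_cols_concat(outs))
}

aifi_flops <- function(l, h, w) {
  n <- h * w
  f <- if (l$m2sa) m2sa_flops(l$block, h, w) else mha_flops(l$block, n, n)
  f + linear_flops(l$ffn1, n) + linear_flops(l$ffn2, n)
}

#' Build the top-level encoder layer (AIFI / M2SA-AIFI)
#'
#' @param cfg an [m2sa_config()], or NULL for the baseline multi-head
#'   attention sublayer.
#' @param ffn feed-forward width.
#' @return an encoder layer; apply it to a (H, W, hidden) map with
#'   `aifi_apply()`.
#' @export
build_m2sa_aifi <- function(cfg = m2sa_config(), ffn = 1024L) {
  if (is.null(cfg)) make_aifi(m2sa = FALSE, ffn = ffn)
  else make_aifi(hidden = cfg$hidden, heads = cfg$heads, ffn = ffn,
                 m2sa = TRUE, m2sa_cfg = cfg)
}

#' @rdname build_m2sa_aifi
#' @param layer a layer built by [build_m2sa_aifi()].
#' @param x numeric (H, W, hidden) array (the projected P5 level).
#' @param level pyramid level tag; anything but `"P5"` is an error, since the
#'   layer performs intra-scale interaction on the top level only.
#' @export
aifi_apply <- function(layer, x, level = "P5")
  val(aifi_fwd(layer, tt(check_map(x)), level))
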