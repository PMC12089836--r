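# Building blocks for the detector: convolution + channel norm + activation,
# linear layers, multi-head attention and 2-D sine-cosine position embeddings.
# Every block carries enough configuration for the analytic profiler to mirror
# its forward pass arithmetically (conv_flops / linear_flops / mha_flops).

conv_out_size <- function(n, k, stride, pad, dil = 1L) {
  (n + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
}

# Kaiming-normal conv weight (kh, kw, cin/groups, cout).
init_conv_w <- function(kh, kw, cinpg, cout) {
  fan_in <- kh * kw * cinpg
  array(stats::rnorm(kh * kw * cinpg * cout, sd = sqrt(2 / fan_in)),
        c(kh, kw, cinpg, cout))
}

init_linear_w <- function(din, dout) {
  lim <- sqrt(6 / (din + dout))
  matrix(stats::runif(din * dout, -lim, lim), din, dout)
}

#' @noRd
make_conv <- function(cin, cout, k = 3L, stride = 1L, dil = 1L, groups = 1L,
                      norm = TRUE, act = c("none", "relu", "silu", "relu6"),
                      bias = !norm, pad = NULL) {
  act <- match.arg(act)
  if (is.null(pad)) pad <- dil * (k - 1L) %/% 2L
  l <- list(kind = "conv", cin = cin, cout = cout, k = k, stride = stride,
            pad = pad, dil = dil, groups = groups, act = act, norm = norm,
            w = tp(init_conv_w(k, k, cin %/% groups, cout)))
  if (bias) l$b <- tp(numeric(cout))
  if (norm) {
    l$gamma <- tp(rep(1, cout))
    l$beta <- tp(numeric(cout))
  }
  l
}

conv_fwd <- function(l, x) {
  y <- t_conv2d(x, l$w, l$b, stride = l$stride, pad = l$pad, dil = l$dil,
                groups = l$groups)
  if (l$norm) y <- t_instnorm(y, l$gamma, l$beta)
  switch(l$act,
         none = y, relu = t_relu(y), silu = t_silu(y), relu6 = t_relu6(y))
}

# Analytic FLOPs (2 x MAC) and output size of a conv block.
conv_flops <- function(l, h, w) {
  ho <- conv_out_size(h, l$k, l$stride, l$pad, l$dil)
  wo <- conv_out_size(w, l$k, l$stride, l$pad, l$dil)
  f <- 2 * l$k * l$k * (l$cin / l$groups) * l$cout * ho * wo
  if (!is.null(l$b)) f <- f + ho * wo * l$cout
  list(f = f, h = ho, w = wo)
}

make_linear <- function(din, dout, bias = TRUE) {
  l <- list(kind = "linear", din = din, dout = dout,
            w = tp(init_linear_w(din, dout)))
  if (bias) l$b <- tp(numeric(dout))
  l
}

linear_fwd <- function(l, x) {
  y <- t_matmul(x, l$w)
  if (!is.null(l$b)) y <- t_add(y, l$b)
  y
}

linear_flops <- function(l, n) {
  2 * n * l$din * l$dout + (if (is.null(l$b)) 0 else n * l$dout)
}

make_layernorm <- function(d) {
  list(kind = "layernorm", d = d, gamma = tp(rep(1, d)), beta = tp(numeric(d)))
}
layernorm_fwd <- function(l, x) t_layernorm(x, l$gamma, l$beta)

# Two-layer MLP head (used for box regression).
make_mlp <- function(din, dhidden, dout, nlayers = 3L) {
  dims <- c(din, rep(dhidden, nlayers - 1L), dout)
  list(kind = "mlp",
       layers = lapply(seq_len(nlayers), function(i)
         make_linear(dims[i], dims[i + 1L])))
}

mlp_fwd <- function(l, x) {
  n <- length(l$layers)
  for (i in seq_len(n)) {
    x <- linear_fwd(l$layers[[i]], x)
    if (i < n) x <- t_relu(x)
  }
  x
}

mlp_flops <- function(l, n) sum(vapply(l$layers, linear_flops, 0, n = n))

# --- multi-head attention ---------------------------------------------------

make_mha <- function(d, heads) {
  list(kind = "mha", d = d, heads = heads,
       wq = make_linear(d, d), wk = make_linear(d, d),
       wv = make_linear(d, d), wo = make_linear(d, d))
}

# q_in: (Lq, d) tokens; kv_in: (Lk, d); mask: optional additive (Lq, Lk)
# constant matrix (use -Inf-like large negatives to forbid attention).
mha_fwd <- function(l, q_in, kv_in, mask = NULL) {
  dh <- l$d %/% l$heads
  q <- linear_fwd(l$wq, q_in)
  k <- linear_fwd(l$wk, kv_in)
  v <- linear_fwd(l$wv, kv_in)
  outs <- vector("list", l$heads)
  for (h in seq_len(l$heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- t_cols(q, cols[1], cols[length(cols)])
    kh <- t_cols(k, cols[1], cols[length(cols)])
    vh <- t_cols(v, cols[1], cols[length(cols)])
    logits <- t_scale(t_matmul(qh, t_transpose(kh)), 1 / sqrt(dh))
    if (!is.null(mask)) logits <- t_add(logits, mask)
    a <- t_softmax_rows(logits)
    outs[[h]] <- t_matmul(a, vh)
  }
  linear_fwd(l$wo, t_cols_concat(outs))
}

mha_flops <- function(l, lq, lk) {
  dh <- l$d / l$heads
  linear_flops(l$wq, lq) + linear_flops(l$wk, lk) + linear_flops(l$wv, lk) +
    linear_flops(l$wo, lq) + 4 * lq * lk * dh * l$heads
}

t_transpose <- function(a) {
  a <- as_wt(a)
  new_node(t(a$v), list(a), function(g) list(t(g)))
}

# --- position embedding -----------------------------------------------------

# 2-D sine-cosine embedding, (H*W, d) in the package token order
# (t = h + (w-1)*H). Deterministic in (H, W, d, temperature).
sine_pos_embed_2d <- function(H, W, d, temperature = 10000) {
  stopifnot(d %% 4 == 0)
  dq <- d %/% 4L
  omega <- 1 / temperature^((seq_len(dq) - 1) / dq)
  hh <- rep(seq_len(H) - 1L, times = W)
  ww <- rep(seq_len(W) - 1L, each = H)
  outw <- outer(ww, omega)   # (HW, dq)
  outh <- outer(hh, omega)
  cbind(sin(outw), cos(outw), sin(outh), cos(outh))
}
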