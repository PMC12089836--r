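# DETR-style decoder: query selection from encoder tokens, optional denoising
# query groups, and a stack of layers with query self-attention, multi-scale
# deformable cross-attention and a feed-forward sublayer. Boxes are predicted
# in normalized cxcywh space by per-layer heads with iterative refinement.

logit_clip <- function(p, eps = 1e-4) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

# gather arbitrary columns (with scatter-add backward)
t_cols_idx <- function(x, idx) {
  x <- as_wt(x); d <- dim(x$v)
  new_node(x$v[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    for (k in seq_along(idx)) gx[, idx[k]] <- gx[, idx[k]] + g[, k]
    list(gx)
  })
}

# sum P row-chunks: (n*p, C) -> (n, C), rows ordered q-fastest within chunks
t_fold_rows <- function(x, n, p) {
  x <- as_wt(x); C <- ncol(x$v)
  v <- matrix(0, n, C)
  for (k in seq_len(p)) v <- v + x$v[((k - 1L) * n + 1L):(k * n), , drop = FALSE]
  new_node(v, list(x), function(g)
    list(do.call(rbind, rep(list(g), p))))
}

make_deform_attn <- function(d = 256L, heads = 8L, levels = 3L, points = 4L) {
  l <- list(kind = "deform_attn", d = d, heads = heads, levels = levels,
            points = points,
            offs = make_linear(d, heads * levels * points * 2L),
            attw = make_linear(d, heads * levels * points),
            value_proj = make_linear(d, d),
            out_proj = make_linear(d, d))
  # zero offset weights; biases arranged on a ring so initial samples spread
  l$offs$w$v[] <- 0
  ang <- 2 * pi * (seq_len(heads) - 1) / heads
  dirs <- cbind(cos(ang), sin(ang))
  dirs <- dirs / apply(abs(dirs), 1L, max)
  bias <- array(0, c(2L, points, levels, heads))
  for (h in seq_len(heads)) for (lv in seq_len(levels))
    for (p in seq_len(points)) bias[, p, lv, h] <- dirs[h, ] * p
  # column layout is [head][level][point][xy] with xy fastest
  bias_cols <- numeric(heads * levels * points * 2L)
  for (h in seq_len(heads)) for (lv in seq_len(levels))
    for (p in seq_len(points)) {
      base <- (((h - 1L) * levels + (lv - 1L)) * points + (p - 1L)) * 2L
      bias_cols[base + 1L:2L] <- bias[, p, lv, h]
    }
  l$offs$b$v[] <- bias_cols
  l$attw$w$v[] <- 0
  l$attw$b$v[] <- 0
  l
}

# query: (Nq, d) tensor (content + position); ref: constant (Nq, 4) cxcywh in
# [0,1]; value_maps: list per level of (H, W, d) tensors.
deform_attn_fwd <- function(l, query, ref, value_maps) {
  nq <- nrow(val(query))
  P <- l$points; L <- l$levels; hd <- l$d %/% l$heads
  offs <- linear_fwd(l$offs, query)          # (Nq, H*L*P*2)
  attw <- linear_fwd(l$attw, query)          # (Nq, H*L*P)
  head_outs <- vector("list", l$heads)
  for (h in seq_len(l$heads)) {
    wh_cols <- ((h - 1L) * L * P + 1L):(h * L * P)
    wsm <- t_softmax_rows(t_cols(attw, wh_cols[1], wh_cols[length(wh_cols)]))
    acc <- NULL
    for (lv in seq_len(L)) {
      dmap <- dim(val(value_maps[[lv]]))
      vmap <- t_cols3(value_maps[[lv]], (h - 1L) * hd + 1L, h * hd)
      base <- (((h - 1L) * L + (lv - 1L)) * P) * 2L
      xcols <- base + 2L * (seq_len(P) - 1L) + 1L
      ycols <- base + 2L * (seq_len(P) - 1L) + 2L
      xs <- t_reshape(t_cols_idx(offs, xcols), c(nq * P, 1L))
      ys <- t_reshape(t_cols_idx(offs, ycols), c(nq * P, 1L))
      sx <- matrix(rep(ref[, 3] * 0.5 / P, P), ncol = 1L)
      sy <- matrix(rep(ref[, 4] * 0.5 / P, P), ncol = 1L)
      cx <- matrix(rep(ref[, 1], P), ncol = 1L)
      cy <- matrix(rep(ref[, 2], P), ncol = 1L)
      px <- t_add(t_scale(t_mul(xs, sx), dmap[2]),
                  matrix(cx * dmap[2] - 0.5, ncol = 1L))
      py <- t_add(t_scale(t_mul(ys, sy), dmap[1]),
                  matrix(cy * dmap[1] - 0.5, ncol = 1L))
      sampled <- t_bilinear_sample(vmap, t_cols_concat(list(px, py)))
      wlv <- t_reshape(t_cols(wsm, (lv - 1L) * P + 1L, lv * P), c(nq * P, 1L))
      contrib <- t_fold_rows(t_mul(sampled, wlv), nq, P)
      acc <- if (is.null(acc)) contrib else t_add(acc, contrib)
    }
    head_outs[[h]] <- acc
  }
  linear_fwd(l$out_proj, t_cols_concat(head_outs))
}

deform_attn_flops <- function(l, nq, ntok) {
  linear_flops(l$offs, nq) + linear_flops(l$attw, nq) +
    linear_flops(l$value_proj, ntok) + linear_flops(l$out_proj, nq)
}

make_decoder_layer <- function(d = 256L, heads = 8L, ffn = 1024L,
                               levels = 3L, points = 4L) {
  list(kind = "decoder_layer",
       self_attn = make_mha(d, heads),
       cross = make_deform_attn(d, heads, levels, points),
       ln1 = make_layernorm(d), ln2 = make_layernorm(d),
       ln3 = make_layernorm(d),
       ffn1 = make_linear(d, ffn), ffn2 = make_linear(ffn, d))
}

decoder_layer_fwd <- function(l, q, qpos, ref, value_maps, mask = NULL) {
  qp <- t_add(q, qpos)
  sa <- if (is.null(mask)) mha_fwd_qk(l$self_attn, qp, qp, q)
        else mha_fwd_qk_masked(l$self_attn, qp, qp, q, mask)
  q <- layernorm_fwd(l$ln1, t_add(q, sa))
  ca <- deform_attn_fwd(l$cross, t_add(q, qpos), ref, value_maps)
  q <- layernorm_fwd(l$ln2, t_add(q, ca))
  f <- linear_fwd(l$ffn2, t_relu(linear_fwd(l$ffn1, q)))
  layernorm_fwd(l$ln3, t_add(q, f))
}

mha_fwd_qk_masked <- function(l, q_in, k_in, v_in, mask) {
  dh <- l$d %/% l$heads
  q <- linear_fwd(l$wq, q_in)
  k <- linear_fwd(l$wk, k_in)
  v <- linear_fwd(l$wv, v_in)
  outs <- vector("list", l$heads)
  for (h in seq_len(l$heads)) {
    a <- ((h - 1L) * dh + 1L); b <- h * dh
    lg <- t_scale(t_matmul(t_cols(q, a, b), t_transpose(t_cols(k, a, b))),
                  1 / sqrt(dh))
    lg <- t_add(lg, mask)
    outs[[h]] <- t_matmul(t_softmax_rows(lg), t_cols(v, a, b))
  }
  linear_fwd(l$wo, t_cols_concat(outs))
}

make_decoder <- function(d = 256L, nc = 2L, layers = 3L, heads = 8L,
                         queries = 300L, ffn = 1024L, levels = 3L,
                         points = 4L, denoising = 100L) {
  dec <- list(kind = "decoder", d = d, nc = nc, nlayers = layers,
              queries = queries, denoising = denoising,
              enc_output = make_linear(d, d),
              enc_ln = make_layernorm(d),
              enc_score = make_linear(d, nc),
              enc_bbox = make_mlp(d, d, 4L, 3L),
              query_pos_head = make_mlp(4L, 2L * d, d, 2L),
              dn_class_embed = tp(matrix(stats::rnorm((nc + 1L) * d,
                                                      sd = 0.02), nc + 1L, d)),
              layers = lapply(seq_len(layers), function(i)
                make_decoder_layer(d, heads, ffn, levels, points)),
              score_heads = lapply(seq_len(layers), function(i)
                make_linear(d, nc)),
              bbox_heads = lapply(seq_len(layers), function(i)
                make_mlp(d, d, 4L, 3L)))
  # focal-style prior on classification logits; zero-initialized final box
  # layers so predictions start exactly at their reference boxes
  for (hd in dec$score_heads) hd$b$v[] <- -log((1 - 0.01) / 0.01)
  dec$enc_score$b$v[] <- -log((1 - 0.01) / 0.01)
  zero_last <- function(mlp) {
    last <- mlp$layers[[length(mlp$layers)]]
    last$w$v[] <- 0
    last$b$v[] <- 0
  }
  for (hd in dec$bbox_heads) zero_last(hd)
  zero_last(dec$enc_bbox)
  dec
}

# Anchors for query selection: one per token, cxcywh in [0,1], logit space.
decoder_anchors <- function(sizes, grid_size = 0.05) {
  anchors <- list(); valid <- list()
  for (lv in seq_along(sizes)) {
    H <- sizes[[lv]][1]; W <- sizes[[lv]][2]
    hh <- rep(seq_len(H) - 0.5, times = W) / H
    ww <- rep(seq_len(W) - 0.5, each = H) / W
    wh <- grid_size * 2^(lv - 1)
    a <- cbind(ww, hh, rep(wh, H * W), rep(wh, H * W))
    v <- apply(a > 0.01 & a < 0.99, 1L, all)
    anchors[[lv]] <- a; valid[[lv]] <- v
  }
  list(logit = logit_clip(do.call(rbind, anchors)),
       valid = unlist(valid))
}

# Denoising query construction for one image's ground truth.
make_dn_queries <- function(dec, gt_boxes, gt_classes, box_noise = 0.4,
                            label_noise = 0.25) {
  ngt <- nrow(gt_boxes)
  if (is.null(ngt) || ngt == 0L || dec$denoising <= 0L) return(NULL)
  groups <- max(1L, dec$denoising %/% max(1L, 2L * ngt))
  pos <- list(); labels <- integer(0); types <- integer(0)
  for (g in seq_len(groups)) {
    for (neg in c(FALSE, TRUE)) {
      b <- gt_boxes
      # shift centres and rescale within the box (positives) or push the box
      # away (negatives, trained as background)
      scale <- if (neg) 1 + box_noise + stats::runif(ngt) * box_noise
               else 1 + (stats::runif(ngt) - 0.5) * box_noise
      b[, 1] <- b[, 1] + (stats::runif(ngt) - 0.5) * box_noise * b[, 3]
      b[, 2] <- b[, 2] + (stats::runif(ngt) - 0.5) * box_noise * b[, 4]
      b[, 3] <- pmin(pmax(b[, 3] * scale, 1e-3), 1)
      b[, 4] <- pmin(pmax(b[, 4] * scale, 1e-3), 1)
      b[, 1] <- pmin(pmax(b[, 1], 0), 1)
      b[, 2] <- pmin(pmax(b[, 2], 0), 1)
      lab <- gt_classes
      flip <- stats::runif(ngt) < label_noise
      lab[flip] <- sample.int(dec$nc, sum(flip), replace = TRUE) - 1L
      pos[[length(pos) + 1L]] <- b
      labels <- c(labels, lab)
      types <- c(types, rep(if (neg) 0L else 1L, ngt))
    }
  }
  boxes <- do.call(rbind, pos)
  list(boxes = boxes, labels = labels, positive = types == 1L,
       groups = groups, per_group = 2L * ngt,
       gt_index = rep(seq_len(ngt), 2L * groups))
}

# Forward pass of the decoder over concatenated level tokens.
# feats: list(N3, N4, N5) maps; dn: output of make_dn_queries() or NULL.
decoder_fwd <- function(dec, feats, dn = NULL) {
  sizes <- lapply(feats, function(f) dim(val(f))[1:2])
  toks <- t_rows_concat(lapply(feats, t_flatten_tokens))
  ntok <- nrow(val(toks))
  anc <- decoder_anchors(sizes)
  mem <- layernorm_fwd(dec$enc_ln, linear_fwd(dec$enc_output, toks))
  enc_logits <- linear_fwd(dec$enc_score, mem)
  enc_delta <- mlp_fwd(dec$enc_bbox, mem)
  enc_boxes <- t_sigmoid(t_add(enc_delta, anc$logit))
  # query selection: top tokens by maximum class logit (invalid anchors out)
  sel_score <- apply(val(enc_logits), 1L, max)
  sel_score[!anc$valid] <- -Inf
  k <- min(dec$queries, ntok)
  sel <- order(sel_score, decreasing = TRUE)[seq_len(k)]
  target <- tt(val(mem)[sel, , drop = FALSE])         # detached content
  ref <- val(enc_boxes)[sel, , drop = FALSE]          # detached boxes
  nq_match <- k
  mask <- NULL
  if (!is.null(dn)) {
    ndn <- nrow(dn$boxes)
    dn_content <- t_rows_gather(dec$dn_class_embed, dn$labels + 1L)
    target <- t_rows_concat(list(dn_content, target))
    ref <- rbind(dn$boxes, ref)
    n <- ndn + k
    mask <- matrix(0, n, n)
    mask[(ndn + 1L):n, seq_len(ndn)] <- -1e9   # matching part blind to dn
    for (g in seq_len(dn$groups)) {            # dn groups blind to each other
      rows <- ((g - 1L) * dn$per_group + 1L):(g * dn$per_group)
      other <- setdiff(seq_len(ndn), rows)
      mask[rows, other] <- -1e9
    }
  }
  starts <- cumsum(c(0L, vapply(sizes, function(s) s[1] * s[2], 0L)))
  out <- list()
  q <- target
  for (li in seq_len(dec$nlayers)) {
    qpos <- mlp_fwd(dec$query_pos_head, tt(ref))
    lay <- dec$layers[[li]]
    value_tok <- linear_fwd(lay$cross$value_proj, toks)
    value_maps <- lapply(seq_along(sizes), function(lv) {
      rows <- (starts[lv] + 1L):starts[lv + 1L]
      t_unflatten_tokens(t_rows_gather(value_tok, rows),
                         sizes[[lv]][1], sizes[[lv]][2])
    })
    q <- decoder_layer_fwd(lay, q, qpos, ref, value_maps, mask)
    logits <- linear_fwd(dec$score_heads[[li]], q)
    boxes <- t_sigmoid(t_add(mlp_fwd(dec$bbox_heads[[li]], q),
                             logit_clip(ref)))
    out[[li]] <- list(logits = logits, boxes = boxes)
    ref <- val(boxes)                                  # detached refinement
  }
  list(layers = out, enc = list(logits = enc_logits, boxes = enc_boxes,
                                sel = sel),
       nq_match = nq_match,
       ndn = if (is.null(dn)) 0L else nrow(dn$boxes))
}

decoder_flops <- function(dec, sizes) {
  ntok <- sum(vapply(sizes, function(s) s[1] * s[2], 0))
  nq <- min(dec$queries, ntok)
  f <- linear_flops(dec$enc_output, ntok) + linear_flops(dec$enc_score, ntok) +
    mlp_flops(dec$enc_bbox, ntok)
  for (li in seq_len(dec$nlayers)) {
    lay <- dec$layers[[li]]
    f <- f + mlp_flops(dec$query_pos_head, nq) +
      mha_flops(lay$self_attn, nq, nq) +
      deform_attn_flops(lay$cross, nq, ntok) +
      linear_flops(lay$ffn1, nq) + linear_flops(lay$ffn2, nq) +
      linear_flops(dec$score_heads[[li]], nq) +
      mlp_flops(dec$bbox_heads[[li]], nq)
  }
  f
}
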