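# Hybrid encoder: 1x1 input projections to the common hidden width, the
# intra-scale interaction layer (AIFI / M2SA-AIFI) on P5, and cross-scale
# fusion - either the baseline CCFF (FPN + PAN with CSPRep blocks) or CSRFPN.

make_repvgg <- function(C) {
  list(kind = "repvgg",
       c3 = make_conv(C, C, k = 3L, act = "none"),
       c1 = make_conv(C, C, k = 1L, act = "none"))
}

repvgg_fwd <- function(l, x)
  t_silu(t_add(conv_fwd(l$c3, x), conv_fwd(l$c1, x)))

repvgg_flops <- function(l, h, w)
  conv_flops(l$c3, h, w)$f + conv_flops(l$c1, h, w)$f

make_csprep <- function(cin, cout, n = 3L, expansion = 0.5) {
  hid <- as.integer(round(cout * expansion))
  l <- list(kind = "csprep", cin = cin, cout = cout, hid = hid,
            conv1 = make_conv(cin, hid, k = 1L, act = "silu"),
            conv2 = make_conv(cin, hid, k = 1L, act = "silu"),
            blocks = lapply(seq_len(n), function(i) make_repvgg(hid)))
  if (hid != cout) l$conv3 <- make_conv(hid, cout, k = 1L, act = "silu")
  l
}

csprep_fwd <- function(l, x) {
  a <- conv_fwd(l$conv1, x)
  for (b in l$blocks) a <- repvgg_fwd(b, a)
  y <- t_add(a, conv_fwd(l$conv2, x))
  if (!is.null(l$conv3)) y <- conv_fwd(l$conv3, y)
  y
}

csprep_flops <- function(l, h, w) {
  f <- conv_flops(l$conv1, h, w)$f + conv_flops(l$conv2, h, w)$f +
    sum(vapply(l$blocks, repvgg_flops, 0, h = h, w = w))
  if (!is.null(l$conv3)) f <- f + conv_flops(l$conv3, h, w)$f
  f
}

make_ccff <- function(C = 256L, depth = 3L, expansion = 0.5) {
  list(kind = "ccff", C = C,
       lateral1 = make_conv(C, C, k = 1L, act = "silu"),
       lateral2 = make_conv(C, C, k = 1L, act = "silu"),
       fpn1 = make_csprep(2L * C, C, depth, expansion),
       fpn2 = make_csprep(2L * C, C, depth, expansion),
       down1 = make_conv(C, C, k = 3L, stride = 2L, act = "silu"),
       down2 = make_conv(C, C, k = 3L, stride = 2L, act = "silu"),
       pan1 = make_csprep(2L * C, C, depth, expansion),
       pan2 = make_csprep(2L * C, C, depth, expansion))
}

ccff_fwd <- function(l, p3, p4, p5) {
  d4 <- dim(val(p4)); d3 <- dim(val(p3))
  h5 <- conv_fwd(l$lateral1, p5)
  f4 <- csprep_fwd(l$fpn1,
                   t_concat_c(list(t_resize_bilinear(h5, d4[1], d4[2]), p4)))
  h4 <- conv_fwd(l$lateral2, f4)
  n3 <- csprep_fwd(l$fpn2,
                   t_concat_c(list(t_resize_bilinear(h4, d3[1], d3[2]), p3)))
  n4 <- csprep_fwd(l$pan1, t_concat_c(list(conv_fwd(l$down1, n3), h4)))
  n5 <- csprep_fwd(l$pan2, t_concat_c(list(conv_fwd(l$down2, n4), h5)))
  list(N3 = n3, N4 = n4, N5 = n5)
}

ccff_flops <- function(l, h3, w3) {
  h4 <- h3 %/% 2L; w4 <- w3 %/% 2L
  h5 <- h3 %/% 4L; w5 <- w3 %/% 4L
  conv_flops(l$lateral1, h5, w5)$f + csprep_flops(l$fpn1, h4, w4) +
    conv_flops(l$lateral2, h4, w4)$f + csprep_flops(l$fpn2, h3, w3) +
    conv_flops(l$down1, h3, w3)$f + csprep_flops(l$pan1, h4, w4) +
    conv_flops(l$down2, h4, w4)$f + csprep_flops(l$pan2, h5, w5)
}

make_encoder <- function(hidden = 256L, use_m2sa = FALSE, use_csrfpn = FALSE,
                         ffn = 1024L, m2sa_cfg = NULL, neck_cfg = NULL) {
  enc <- list(kind = "encoder", hidden = hidden,
              use_m2sa = use_m2sa, use_csrfpn = use_csrfpn,
              proj3 = make_conv(128L, hidden, k = 1L, act = "none"),
              proj4 = make_conv(256L, hidden, k = 1L, act = "none"),
              proj5 = make_conv(512L, hidden, k = 1L, act = "none"))
  enc$aifi <- if (use_m2sa)
    build_m2sa_aifi(if (is.null(m2sa_cfg)) m2sa_config(hidden = hidden)
                    else m2sa_cfg, ffn = ffn)
  else make_aifi(hidden = hidden, ffn = ffn, m2sa = FALSE)
  enc$neck <- if (use_csrfpn)
    build_csrfpn(if (is.null(neck_cfg)) neck_config(hidden = hidden)
                 else neck_cfg)
  else make_ccff(hidden)
  enc
}

encoder_fwd <- function(enc, feats) {
  p3 <- conv_fwd(enc$proj3, feats$P3)
  p4 <- conv_fwd(enc$proj4, feats$P4)
  p5 <- conv_fwd(enc$proj5, feats$P5)
  p5 <- aifi_fwd(enc$aifi, p5)
  if (enc$use_csrfpn) csrfpn_fwd(enc$neck, p3, p4, p5)
  else ccff_fwd(enc$neck, p3, p4, p5)
}

encoder_flops <- function(enc, h3, w3) {
  h4 <- h3 %/% 2L; w4 <- w3 %/% 2L
  h5 <- h3 %/% 4L; w5 <- w3 %/% 4L
  f <- conv_flops(enc$proj3, h3, w3)$f + conv_flops(enc$proj4, h4, w4)$f +
    conv_flops(enc$proj5, h5, w5)$f + aifi_flops(enc$aifi, h5, w5)
  f + if (enc$use_csrfpn) csrfpn_flops(enc$neck, h3, w3)
      else ccff_flops(enc$neck, h3, w3)
}
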