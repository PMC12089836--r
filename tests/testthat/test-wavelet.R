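# Haar wavelet pair, WTConv operator and the closed-form FLOP calculators.

test_that("Haar analysis matches hand-computed coefficients", {
  # single 2x2 block, rows (1 2 / 3 4); frozen from an independent separable
  # filtering oracle: LL = 5, column-difference -1, row-difference -2, diag 0
  x <- matrix(c(1, 3, 2, 4), 2, 2)   # column-major: rows are (1,2),(3,4)
  s <- haar_dwt2(x)
  expect_equal(as.numeric(s$LL), 5)
  expect_equal(as.numeric(s$LH), -1)  # horizontal (column) detail
  expect_equal(as.numeric(s$HL), -2)  # vertical (row) detail
  expect_equal(as.numeric(s$HH), 0)
  # constant map: low-pass doubles the value, all detail vanishes
  v <- 3.7
  s2 <- haar_dwt2(array(v, c(6, 6, 2)))
  expect_equal(s2$LL, array(2 * v, c(3, 3, 2)))
  expect_equal(max(abs(s2$LH), abs(s2$HL), abs(s2$HH)), 0)
  expect_error(haar_dwt2(array(0, c(0, 4, 1))), "non-empty")
})

test_that("Haar pair reconstructs perfectly and conserves energy", {
  set.seed(42)
  for (n in c(4L, 8L, 16L, 64L)) {
    x <- array(rnorm(n * n * 2), c(n, n, 2))
    s <- haar_dwt2(x)
    expect_lt(max(abs(haar_idwt2(s) - x)) / max(abs(x)), 1e-5)
    energy_in <- sum(x^2)
    energy_sb <- sum(s$LL^2) + sum(s$LH^2) + sum(s$HL^2) + sum(s$HH^2)
    expect_equal(energy_sb, energy_in, tolerance = 1e-10)
    # round trip the other way: dwt(idwt(s)) = s
    s2 <- haar_dwt2(haar_idwt2(s))
    expect_lt(max(abs(s2$LL - s$LL)), 1e-10)
  }
  # inverse of the constant example; zeros map to zeros (linearity)
  z <- array(0, c(3, 3, 1))
  expect_equal(haar_idwt2(list(LL = z + 4, LH = z, HL = z, HH = z)),
               array(2, c(6, 6, 1)))
  expect_equal(haar_idwt2(list(LL = z, LH = z, HL = z, HH = z)),
               array(0, c(6, 6, 1)))
  expect_error(haar_idwt2(list(LL = z, LH = z, HL = z,
                               HH = array(0, c(2, 3, 1)))), "match")
})

# Independent WTConv oracle: naive loops, no engine code. Depthwise "same"
# convolution and the level cascade written directly from the definition.
naive_dwconv <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  kk <- dim(k)[1]; r <- (kk - 1) / 2
  out <- array(0, d)
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in seq_len(kk)) for (b in seq_len(kk)) {
      ii <- i + a - 1 - r; jj <- j + b - 1 - r
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, c] * k[a, b, 1, c]
    }
    out[i, j, c] <- acc
  }
  out
}

naive_dwt <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] / 2, d[2] / 2, 4 * d[3]))
  C <- d[3]
  for (c in seq_len(C)) for (i in seq_len(d[1] / 2)) for (j in seq_len(d[2] / 2)) {
    p <- x[2 * i - 1, 2 * j - 1, c]; q <- x[2 * i - 1, 2 * j, c]
    s <- x[2 * i, 2 * j - 1, c]; t <- x[2 * i, 2 * j, c]
    out[i, j, c] <- (p + q + s + t) / 2
    out[i, j, C + c] <- (p - q + s - t) / 2
    out[i, j, 2 * C + c] <- (p + q - s - t) / 2
    out[i, j, 3 * C + c] <- (p - q - s + t) / 2
  }
  out
}

naive_idwt <- function(sb) {
  d <- dim(sb); C <- d[3] / 4
  out <- array(0, c(2 * d[1], 2 * d[2], C))
  for (c in seq_len(C)) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ll <- sb[i, j, c]; lh <- sb[i, j, C + c]
    hl <- sb[i, j, 2 * C + c]; hh <- sb[i, j, 3 * C + c]
    out[2 * i - 1, 2 * j - 1, c] <- (ll + lh + hl + hh) / 2
    out[2 * i - 1, 2 * j, c] <- (ll - lh + hl - hh) / 2
    out[2 * i, 2 * j - 1, c] <- (ll + lh - hl - hh) / 2
    out[2 * i, 2 * j, c] <- (ll - lh - hl + hh) / 2
  }
  out
}

naive_wtconv <- function(x, weights, levels) {
  cascade <- function(cur, lev) {
    sb <- naive_dwt(cur)
    C <- dim(cur)[3]
    conv <- naive_dwconv(sb, weights$bands[[lev]])
    if (lev < levels) {
      deeper <- cascade(sb[, , seq_len(C), drop = FALSE], lev + 1)
      conv[, , seq_len(C)] <- conv[, , seq_len(C), drop = FALSE] + deeper
    }
    naive_idwt(conv)
  }
  naive_dwconv(x, weights$base) + cascade(x, 1)
}

test_that("wtconv2d equals the naive-loop oracle on small inputs", {
  set.seed(11)
  for (case in list(list(n = 4L, C = 1L, lev = 1L, k = 3L, bk = 3L),
                    list(n = 8L, C = 2L, lev = 2L, k = 3L, bk = 5L),
                    list(n = 8L, C = 3L, lev = 1L, k = 1L, bk = 1L))) {
    x <- array(rnorm(case$n^2 * case$C), c(case$n, case$n, case$C))
    cfg <- wtconv_config(levels = case$lev, band_kernel = case$k,
                         channels = case$C, base_kernel = case$bk)
    w <- list(base = array(rnorm(case$bk^2 * case$C),
                           c(case$bk, case$bk, 1, case$C)),
              bands = lapply(seq_len(case$lev), function(i)
                array(rnorm(case$k^2 * 4 * case$C),
                      c(case$k, case$k, 1, 4 * case$C))))
    expect_lt(max(abs(wtconv2d(x, cfg, w) - naive_wtconv(x, w, case$lev))),
              1e-5)
  }
})

test_that("wtconv2d algebraic forcings hold", {
  set.seed(12)
  x <- array(rnorm(64), c(8, 8, 1))
  cfg <- wtconv_config(levels = 1, band_kernel = 1, base_kernel = 1)
  # zero weights annihilate; identity base with zero bands is the identity
  zero <- list(base = array(0, c(1, 1, 1, 1)),
               bands = list(array(0, c(1, 1, 1, 4))))
  expect_equal(wtconv2d(x, cfg, zero), array(0, dim(x)))
  ident <- list(base = array(1, c(1, 1, 1, 1)),
                bands = list(array(0, c(1, 1, 1, 4))))
  expect_equal(wtconv2d(x, cfg, ident), x)
  # scalar band kernels c on every band with zero base scale a constant
  # input by c (dwt -> scale -> idwt is c times the identity)
  cc <- 0.7
  sc <- list(base = array(0, c(1, 1, 1, 1)),
             bands = list(array(cc, c(1, 1, 1, 4))))
  v <- array(2.5, c(8, 8, 1))
  expect_equal(wtconv2d(v, cfg, sc), cc * v, tolerance = 1e-12)
  # too many levels for the input errors with the limiting level
  cfg_deep <- wtconv_config(levels = 4, band_kernel = 1, base_kernel = 1)
  wdeep <- list(base = zero$base,
                bands = rep(list(array(0, c(1, 1, 1, 4))), 4))
  expect_error(wtconv2d(x, cfg_deep, wdeep), "level")
})

test_that("FLOP calculators evaluate the closed-form sums", {
  expect_equal(flops_wt(16, 64, 64, 2), 393216)
  expect_equal(flops_bands(16, 16, 64, 64, 3, 1), 18874368)
  # decomposition and reconstruction counts are symmetric in the channel count
  expect_equal(flops_iwt(16, 64, 64, 2), flops_wt(16, 64, 64, 2))
  expect_error(flops_wt(16, 64, 64, 0), "positive")
  expect_error(flops_bands(-1, 16, 64, 64, 3, 1), "positive")
  # growth: linear in k^2 and in C_in*C_out
  expect_equal(flops_bands(16, 16, 64, 64, 6, 1) /
                 flops_bands(16, 16, 64, 64, 3, 1), 4)
  expect_equal(flops_bands(32, 16, 64, 64, 3, 1) /
                 flops_bands(16, 16, 64, 64, 3, 1), 2)
  # cheaper than a dense conv with the equivalent receptive field K = 2^l k
  for (l in 1:3) {
    k <- 3; K <- 2^l * k
    dense <- 2 * K^2 * 16 * 16 * 64 * 64
    expect_lt(flops_wt(16, 64, 64, l) + flops_bands(16, 16, 64, 64, k, l) +
                flops_iwt(16, 64, 64, l), dense)
  }
})

test_that("backbone produces the stride-8/16/32 pyramid and WTConv shrinks it", {
  ns <- asNamespace("wmcdetr")
  set.seed(1)
  bb <- build_wt_backbone(wt = FALSE)
  x <- ns$tt(array(rnorm(128 * 128 * 3), c(128, 128, 3)))
  f <- ns$backbone_fwd(bb, x)
  expect_equal(dim(ns$val(f$P3)), c(16L, 16L, 128L))
  expect_equal(dim(ns$val(f$P4)), c(8L, 8L, 256L))
  expect_equal(dim(ns$val(f$P5)), c(4L, 4L, 512L))
  # deterministic forward under fixed weights
  f2 <- ns$backbone_fwd(bb, x)
  expect_identical(ns$val(f$P5), ns$val(f2$P5))
  nparams <- function(m) sum(vapply(ns$collect_params(m),
                                    function(p) length(p$v), 0))
  set.seed(1)
  wtbb <- build_wt_backbone(wt = TRUE, policy = "balanced")
  expect_lt(nparams(wtbb), nparams(bb))
  expect_error(build_wt_backbone(policy = "bogus"), "unknown")
})
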