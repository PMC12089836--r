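# Minimal reverse-mode automatic differentiation on R arrays.
#
# A graph node ("wt" tensor) is an environment holding a value, an optional
# gradient, its parent nodes and a backward closure. Graphs are built eagerly;
# because parents are always created before children, node ids give a valid
# topological order and backward() simply sweeps ids in decreasing order.
# Feature maps are (H, W, C) arrays; token matrices are (N, D).

.wmc <- new.env(parent = emptyenv())
.wmc$node_id <- 0L

new_node <- function(v, parents = list(), bw = NULL, req = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$parents <- parents
  e$bw <- bw
  e$req <- if (!is.null(req)) req
           else any(vapply(parents, function(p) p$req, logical(1)))
  .wmc$node_id <- .wmc$node_id + 1L
  e$id <- .wmc$node_id
  e$grad <- NULL
  e$param <- FALSE
  class(e) <- "wt"
  e
}

#' @export
print.wt <- function(x, ...) {
  d <- dim(x$v)
  cat("<wt tensor", if (is.null(d)) length(x$v) else paste(d, collapse = "x"),
      if (x$param) "(param)" else "", ">\n")
  invisible(x)
}

tt <- function(v) new_node(v, req = FALSE)                 # constant
tp <- function(v) { n <- new_node(v, req = TRUE); n$param <- TRUE; n }
val <- function(x) if (inherits(x, "wt")) x$v else x
as_wt <- function(x) if (inherits(x, "wt")) x else tt(x)

dims_of <- function(v) { d <- dim(v); if (is.null(d)) length(v) else d }

# Broadcast expansion of `v` to full dims `d` (limited, explicit cases).
bc_expand <- function(v, d) {
  dv <- dims_of(v)
  if (identical(dv, d)) return(v)
  if (length(v) == 1L) return(array(v, dim = d))
  if (length(d) == 3L) {
    if (length(dv) == 3L && dv[1] == 1L && dv[2] == 1L && dv[3] == d[3])
      return(array(rep(as.vector(v), each = d[1] * d[2]), dim = d))
    if (length(dv) == 3L && dv[3] == 1L && dv[1] == d[1] && dv[2] == d[2])
      return(array(rep(as.vector(v), d[3]), dim = d))
  }
  if (length(d) == 2L) {
    if (length(dv) == 1L && dv == d[2])          # row vector over rows
      return(matrix(v, d[1], d[2], byrow = TRUE))
    if (length(dv) == 2L && dv[1] == d[1] && dv[2] == 1L)  # column over cols
      return(matrix(as.vector(v), d[1], d[2]))
    if (length(dv) == 2L && dv[1] == 1L && dv[2] == d[2])
      return(matrix(as.vector(v), d[1], d[2], byrow = TRUE))
  }
  stop("cannot broadcast shape (", paste(dv, collapse = ","),
       ") to (", paste(d, collapse = ","), ")")
}

# Reduce gradient `g` (full dims) back to parent dims `dv` by summation.
bc_reduce <- function(g, dv) {
  d <- dims_of(g)
  if (identical(d, dv)) return(g)
  if (length(dv) == 1L && dv == 1L || (length(dv) == 0L)) return(sum(g))
  if (prod(dv) == 1L) return(array(sum(g), dim = dv))
  if (length(d) == 3L) {
    if (length(dv) == 3L && dv[1] == 1L && dv[2] == 1L)
      return(array(colSums(matrix(g, d[1] * d[2], d[3])), dim = dv))
    if (length(dv) == 3L && dv[3] == 1L)
      return(array(rowSums(matrix(g, d[1] * d[2], d[3])), dim = dv))
  }
  if (length(d) == 2L) {
    if (length(dv) == 1L && dv == d[2]) return(colSums(g))
    if (length(dv) == 2L && dv[2] == 1L) return(matrix(rowSums(g), dv[1], 1L))
    if (length(dv) == 2L && dv[1] == 1L) return(matrix(colSums(g), 1L, dv[2]))
  }
  stop("cannot reduce gradient to shape (", paste(dv, collapse = ","), ")")
}

broadcast_dims <- function(da, db) if (prod(da) >= prod(db)) da else db

t_add <- function(a, b) {
  a <- as_wt(a); b <- as_wt(b)
  da <- dims_of(a$v); db <- dims_of(b$v)
  d <- broadcast_dims(da, db)
  v <- bc_expand(a$v, d) + bc_expand(b$v, d)
  new_node(v, list(a, b), function(g)
    list(bc_reduce(g, da), bc_reduce(g, db)))
}

t_sub <- function(a, b) {
  a <- as_wt(a); b <- as_wt(b)
  da <- dims_of(a$v); db <- dims_of(b$v)
  d <- broadcast_dims(da, db)
  v <- bc_expand(a$v, d) - bc_expand(b$v, d)
  new_node(v, list(a, b), function(g)
    list(bc_reduce(g, da), -bc_reduce(g, db)))
}

t_mul <- function(a, b) {
  a <- as_wt(a); b <- as_wt(b)
  da <- dims_of(a$v); db <- dims_of(b$v)
  d <- broadcast_dims(da, db)
  ae <- bc_expand(a$v, d); be <- bc_expand(b$v, d)
  new_node(ae * be, list(a, b), function(g)
    list(bc_reduce(g * be, da), bc_reduce(g * ae, db)))
}

t_div <- function(a, b) {
  a <- as_wt(a); b <- as_wt(b)
  da <- dims_of(a$v); db <- dims_of(b$v)
  d <- broadcast_dims(da, db)
  ae <- bc_expand(a$v, d); be <- bc_expand(b$v, d)
  new_node(ae / be, list(a, b), function(g)
    list(bc_reduce(g / be, da), bc_reduce(-g * ae / (be * be), db)))
}

t_scale <- function(a, s) {
  a <- as_wt(a)
  new_node(a$v * s, list(a), function(g) list(g * s))
}

t_matmul <- function(a, b) {
  a <- as_wt(a); b <- as_wt(b)
  av <- a$v; bv <- b$v
  if (!is.null(.wmc$flops))
    .wmc$flops <- .wmc$flops + 2 * nrow(av) * ncol(av) * ncol(bv)
  new_node(av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), t(av) %*% g))
}

# FLOP metering: while enabled, t_conv2d and t_matmul accumulate a
# 2-ops-per-multiply-accumulate count from the shapes they actually execute.
# This is the hook-based cross-check for the analytic profiler.
flops_meter_start <- function() .wmc$flops <- 0
flops_meter_stop <- function() { f <- .wmc$flops; .wmc$flops <- NULL; f }

t_relu <- function(a) {
  a <- as_wt(a); m <- a$v > 0
  new_node(a$v * m, list(a), function(g) list(g * m))
}

t_relu6 <- function(a) {
  a <- as_wt(a); m <- a$v > 0 & a$v < 6
  new_node(pmin(pmax(a$v, 0), 6), list(a), function(g) list(g * m))
}

t_sigmoid <- function(a) {
  a <- as_wt(a); s <- 1 / (1 + exp(-a$v))
  new_node(s, list(a), function(g) list(g * s * (1 - s)))
}

t_hsigmoid <- function(a) {
  a <- as_wt(a)
  v <- pmin(pmax(a$v + 3, 0), 6) / 6
  m <- a$v > -3 & a$v < 3
  new_node(v, list(a), function(g) list(g * m / 6))
}

t_silu <- function(a) {
  a <- as_wt(a); s <- 1 / (1 + exp(-a$v))
  new_node(a$v * s, list(a), function(g) list(g * (s + a$v * s * (1 - s))))
}

t_abs <- function(a) {
  a <- as_wt(a); sg <- sign(a$v)
  new_node(abs(a$v), list(a), function(g) list(g * sg))
}

t_sum <- function(a) {
  a <- as_wt(a); d <- dims_of(a$v)
  new_node(sum(a$v), list(a), function(g) list(array(g, dim = d)))
}

t_mean <- function(a) {
  a <- as_wt(a); d <- dims_of(a$v); n <- length(a$v)
  new_node(mean(a$v), list(a), function(g) list(array(g / n, dim = d)))
}

t_minimum <- function(a, b) {
  a <- as_wt(a); b <- as_wt(b)
  m <- a$v <= b$v
  new_node(pmin(a$v, b$v), list(a, b), function(g) list(g * m, g * !m))
}

t_maximum <- function(a, b) {
  a <- as_wt(a); b <- as_wt(b)
  m <- a$v >= b$v
  new_node(pmax(a$v, b$v), list(a, b), function(g) list(g * m, g * !m))
}

t_clamp_min <- function(a, lo) {
  a <- as_wt(a); m <- a$v > lo
  new_node(pmax(a$v, lo), list(a), function(g) list(g * m))
}

# --- convolution / pooling (compiled kernels) -------------------------------

t_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L,
                     groups = 1L) {
  x <- as_wt(x); w <- as_wt(w)
  if (!is.null(b)) b <- as_wt(b)
  dx <- dim(x$v); dw <- dim(w$v)
  H <- dx[1]; W <- dx[2]; Cin <- dx[3]
  kh <- dw[1]; kw <- dw[2]; cout <- dw[4]
  stopifnot(dw[3] * groups == Cin)
  ho <- conv_out_size(H, kh, stride, pad, dil)
  wo <- conv_out_size(W, kw, stride, pad, dil)
  keep <- (w$req || x$req) &&
    (kh * kw * (Cin / groups) * ho * wo * groups) <= 2^18
  r0 <- conv2d_fw_cpp(x$v, w$v, if (is.null(b)) NULL else as.vector(b$v),
                      H, W, Cin, kh, kw, cout, stride, pad, pad, dil, groups,
                      keep)
  v <- r0$out
  col <- if (keep) r0$col else NULL
  if (!is.null(.wmc$flops)) {
    dv <- dim(v)
    .wmc$flops <- .wmc$flops +
      2 * kh * kw * (Cin / groups) * cout * dv[1] * dv[2] +
      (if (is.null(b)) 0 else dv[1] * dv[2] * cout)
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(v, parents, function(g) {
    r <- conv2d_bw_cpp(x$v, w$v, g, H, W, Cin, kh, kw, cout,
                       stride, pad, pad, dil, groups, x$req, !is.null(b), col)
    gw <- r$gw; dim(gw) <- dw
    out <- list(if (x$req) r$gx else NULL, gw)
    if (!is.null(b)) out <- c(out, list(r$gb))
    out
  })
}

t_maxpool <- function(x, k, stride, pad = 0L) {
  x <- as_wt(x); d <- dim(x$v)
  r <- maxpool_fw_cpp(x$v, d[1], d[2], d[3], k, stride, pad)
  idx <- r$idx
  new_node(r$out, list(x), function(g)
    list(maxpool_bw_cpp(g, idx, d[1], d[2], d[3])))
}

t_avgpool <- function(x, f) {
  x <- as_wt(x); d <- dim(x$v)
  H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% f == 0L, W %% f == 0L)
  h2 <- H %/% f; w2 <- W %/% f
  pool <- function(v) {
    a <- colMeans(array(v, c(f, h2, W, C)), dims = 1L)       # (h2, W, C)
    b <- aperm(a, c(2L, 1L, 3L))                             # (W, h2, C)
    b <- colMeans(array(b, c(f, w2, h2, C)), dims = 1L)      # (w2, h2, C)
    aperm(b, c(2L, 1L, 3L))
  }
  new_node(pool(x$v), list(x), function(g) {
    gg <- g / (f * f)
    e1 <- array(rep(as.vector(aperm(gg, c(2L, 1L, 3L))), each = f),
                c(W, h2, C))
    e1 <- aperm(e1, c(2L, 1L, 3L))                           # (h2, W, C)
    gx <- array(rep(as.vector(e1), each = f), c(H, W, C))
    list(gx)
  })
}

t_gap <- function(x) {
  x <- as_wt(x); d <- dim(x$v)
  m <- colMeans(matrix(x$v, d[1] * d[2], d[3]))
  new_node(array(m, c(1L, 1L, d[3])), list(x), function(g)
    list(array(rep(as.vector(g) / (d[1] * d[2]), each = d[1] * d[2]), dim = d)))
}

# --- normalization ----------------------------------------------------------

t_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_wt(x); gamma <- as_wt(gamma); beta <- as_wt(beta)
  d <- dim(x$v); m <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x$v, m, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  gv <- as.vector(gamma$v); bv <- as.vector(beta$v)
  y <- sweep(sweep(xhat, 2L, gv, `*`), 2L, bv, `+`)
  new_node(array(y, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, m, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2L, gv, `*`)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), `*`)
    dx <- sweep(t1 - t2, 2L, istd, `*`)
    list(array(dx, d), dgamma, dbeta)
  })
}

t_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_wt(x); gamma <- as_wt(gamma); beta <- as_wt(beta)
  xm <- x$v; D <- ncol(xm)
  mu <- rowMeans(xm)
  xc <- xm - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- as.vector(gamma$v); bv <- as.vector(beta$v)
  y <- sweep(sweep(xhat, 2L, gv, `*`), 2L, bv, `+`)
  new_node(y, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2L, gv, `*`)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
    list(dx, dgamma, dbeta)
  })
}

t_softmax_rows <- function(x) {
  x <- as_wt(x)
  z <- x$v - apply(x$v, 1L, max)
  e <- exp(z)
  y <- e / rowSums(e)
  new_node(y, list(x), function(g) {
    s <- rowSums(g * y)
    list((g - s) * y)
  })
}

# --- shape plumbing ---------------------------------------------------------

t_reshape <- function(x, d) {
  x <- as_wt(x); d0 <- dims_of(x$v)
  v <- x$v; dim(v) <- d
  new_node(v, list(x), function(g) { dim(g) <- d0; list(g) })
}

# (H, W, C) map -> (H*W, C) tokens; token t corresponds to (h, w) with
# t = h + (w-1)*H (column-major order).
t_flatten_tokens <- function(x) {
  d <- dim(val(x))
  t_reshape(x, c(d[1] * d[2], d[3]))
}

t_unflatten_tokens <- function(x, H, W) {
  d <- dim(val(x))
  t_reshape(x, c(H, W, d[2]))
}

t_cols <- function(x, from, to) {
  x <- as_wt(x); d <- dim(x$v)
  new_node(x$v[, from:to, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2]); gx[, from:to] <- g; list(gx)
  })
}

t_rows_gather <- function(x, idx) {
  x <- as_wt(x); d <- dim(x$v)
  new_node(x$v[idx, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    for (k in seq_along(idx)) gx[idx[k], ] <- gx[idx[k], ] + g[k, ]
    list(gx)
  })
}

t_rows_concat <- function(lst) {
  lst <- lapply(lst, as_wt)
  ns <- vapply(lst, function(t) nrow(t$v), integer(1))
  v <- do.call(rbind, lapply(lst, val))
  ends <- cumsum(ns)
  starts <- c(1L, head(ends, -1L) + 1L)
  new_node(v, lst, function(g)
    lapply(seq_along(lst), function(k) g[starts[k]:ends[k], , drop = FALSE]))
}

t_cols_concat <- function(lst) {
  lst <- lapply(lst, as_wt)
  ns <- vapply(lst, function(t) ncol(t$v), integer(1))
  v <- do.call(cbind, lapply(lst, val))
  ends <- cumsum(ns)
  starts <- c(1L, head(ends, -1L) + 1L)
  new_node(v, lst, function(g)
    lapply(seq_along(lst), function(k) g[, starts[k]:ends[k], drop = FALSE]))
}

t_concat_c <- function(lst) {
  lst <- lapply(lst, as_wt)
  ds <- lapply(lst, function(t) dim(t$v))
  H <- ds[[1]][1]; W <- ds[[1]][2]
  cs <- vapply(ds, function(d) d[3], numeric(1))
  v <- array(unlist(lapply(lst, val), use.names = FALSE), c(H, W, sum(cs)))
  ends <- cumsum(cs)
  starts <- c(1, head(ends, -1) + 1)
  new_node(v, lst, function(g)
    lapply(seq_along(lst), function(k)
      g[, , starts[k]:ends[k], drop = FALSE]))
}

# --- bilinear interpolation -------------------------------------------------

# Interpolation matrix (out x n) for half-pixel-centre alignment.
interp_matrix <- function(n_out, n_in) {
  L <- matrix(0, n_out, n_in)
  if (n_in == 1L) { L[, 1L] <- 1; return(L) }
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src); fr <- src - i0
  i0 <- as.integer(i0); i1 <- pmin(i0 + 1L, n_in - 1L)
  for (k in seq_len(n_out)) {
    L[k, i0[k] + 1L] <- L[k, i0[k] + 1L] + (1 - fr[k])
    L[k, i1[k] + 1L] <- L[k, i1[k] + 1L] + fr[k]
  }
  L
}

apply_hw <- function(v, Lh, Lw) {
  d <- dim(v); H <- d[1]; W <- d[2]; C <- d[3]
  oh <- nrow(Lh); ow <- nrow(Lw)
  a <- Lh %*% matrix(v, H, W * C)                    # (oh, W*C)
  a <- aperm(array(a, c(oh, W, C)), c(2L, 1L, 3L))   # (W, oh, C)
  b <- Lw %*% matrix(a, W, oh * C)                   # (ow, oh*C)
  aperm(array(b, c(ow, oh, C)), c(2L, 1L, 3L))       # (oh, ow, C)
}

t_resize_bilinear <- function(x, oh, ow) {
  x <- as_wt(x); d <- dim(x$v)
  if (d[1] == oh && d[2] == ow) return(x)
  Lh <- interp_matrix(oh, d[1]); Lw <- interp_matrix(ow, d[2])
  new_node(apply_hw(x$v, Lh, Lw), list(x), function(g)
    list(apply_hw(g, t(Lh), t(Lw))))
}

# Sample map (H, W, C) at continuous 0-based pixel coords (N x 2: x, y);
# zero padding outside; returns (N, C). Gradients w.r.t. map and coords.
t_bilinear_sample <- function(map, coords) {
  map <- as_wt(map); coords <- as_wt(coords)
  d <- dim(map$v); H <- d[1]; W <- d[2]; C <- d[3]
  px <- coords$v[, 1L]; py <- coords$v[, 2L]
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  corner <- function(xi, yi) {
    ok <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
    idx <- pmin(pmax(yi, 0), H - 1) + H * pmin(pmax(xi, 0), W - 1)
    vm <- matrix(map$v, H * W, C)[idx + 1L, , drop = FALSE]
    vm[!ok, ] <- 0
    list(v = vm, ok = ok, idx = idx)
  }
  c00 <- corner(x0, y0);     c10 <- corner(x0 + 1, y0)
  c01 <- corner(x0, y0 + 1); c11 <- corner(x0 + 1, y0 + 1)
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  v <- c00$v * w00 + c10$v * w10 + c01$v * w01 + c11$v * w11
  new_node(v, list(map, coords), function(g) {
    gmap <- NULL
    if (map$req) {
      ids <- integer(0); contrib <- NULL
      for (cw in list(list(c00, w00), list(c10, w10),
                      list(c01, w01), list(c11, w11))) {
        sel <- which(cw[[1]]$ok)
        if (length(sel)) {
          ids <- c(ids, cw[[1]]$idx[sel] + 1L)
          block <- g[sel, , drop = FALSE] * cw[[2]][sel]
          contrib <- if (is.null(contrib)) block else rbind(contrib, block)
        }
      }
      gm <- matrix(0, H * W, C)
      if (length(ids)) {
        agg <- rowsum(contrib, group = ids, reorder = FALSE)
        gm[as.integer(rownames(agg)), ] <- agg
      }
      gmap <- array(gm, d)
    }
    gcoords <- NULL
    if (coords$req) {
      dot <- function(cn) rowSums(g * cn$v)
      s00 <- dot(c00); s10 <- dot(c10); s01 <- dot(c01); s11 <- dot(c11)
      gpx <- (s10 - s00) * (1 - fy) + (s11 - s01) * fy
      gpy <- (s01 - s00) * (1 - fx) + (s11 - s10) * fx
      gcoords <- cbind(gpx, gpy)
    }
    list(gmap, gcoords)
  })
}

# --- Haar subband stack (linear, orthonormal) -------------------------------

haar_analysis <- function(v) {
  d <- dim(v); H <- d[1]; W <- d[2]; C <- d[3]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  p <- v[ro, co, , drop = FALSE]; q <- v[ro, ce, , drop = FALSE]
  s <- v[re, co, , drop = FALSE]; t <- v[re, ce, , drop = FALSE]
  ll <- (p + q + s + t) / 2; lh <- (p - q + s - t) / 2
  hl <- (p + q - s - t) / 2; hh <- (p - q - s + t) / 2
  out <- array(0, c(H / 2, W / 2, 4L * C))
  out[, , seq_len(C)] <- ll
  out[, , C + seq_len(C)] <- lh
  out[, , 2L * C + seq_len(C)] <- hl
  out[, , 3L * C + seq_len(C)] <- hh
  out
}

haar_synthesis <- function(sb) {
  d <- dim(sb); h <- d[1]; w <- d[2]; C <- d[3] / 4L
  ll <- sb[, , seq_len(C), drop = FALSE]
  lh <- sb[, , C + seq_len(C), drop = FALSE]
  hl <- sb[, , 2L * C + seq_len(C), drop = FALSE]
  hh <- sb[, , 3L * C + seq_len(C), drop = FALSE]
  out <- array(0, c(2L * h, 2L * w, C))
  ro <- seq(1L, 2L * h, 2L); re <- seq(2L, 2L * h, 2L)
  co <- seq(1L, 2L * w, 2L); ce <- seq(2L, 2L * w, 2L)
  out[ro, co, ] <- (ll + lh + hl + hh) / 2
  out[ro, ce, ] <- (ll - lh + hl - hh) / 2
  out[re, co, ] <- (ll + lh - hl - hh) / 2
  out[re, ce, ] <- (ll - lh - hl + hh) / 2
  out
}

t_dwt_haar <- function(x) {
  x <- as_wt(x)
  new_node(haar_analysis(x$v), list(x), function(g) list(haar_synthesis(g)))
}

t_idwt_haar <- function(sb) {
  sb <- as_wt(sb)
  new_node(haar_synthesis(sb$v), list(sb), function(g) list(haar_analysis(g)))
}

# --- losses -----------------------------------------------------------------

# Sum of element-wise binary cross-entropy with logits (stable form),
# optionally weighted. `target` and `weight` are plain arrays.
t_bce_logits <- function(logits, target, weight = NULL) {
  logits <- as_wt(logits)
  x <- logits$v
  s <- 1 / (1 + exp(-x))
  # log(1 + exp(x)) - t*x, computed stably
  sp <- ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
  per <- sp - target * x
  if (!is.null(weight)) per <- per * weight
  new_node(sum(per), list(logits), function(g) {
    gr <- (s - target)
    if (!is.null(weight)) gr <- gr * weight
    list(g * gr)
  })
}

# --- backward sweep and optimizer -------------------------------------------

backward <- function(out, grad = NULL) {
  stopifnot(inherits(out, "wt"))
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L); nn <- 0L
  stack <- list(out)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- n
    for (p in n$parents) if (p$req) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ids <- vapply(nodes, function(n) n$id, numeric(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  out$grad <- if (!is.null(grad)) grad
              else if (length(out$v) == 1L) 1
              else array(1, dim = dims_of(out$v))
  for (n in nodes) {
    if (is.null(n$bw) || is.null(n$grad)) next
    gs <- n$bw(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (!p$req || k > length(gs) || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
    if (!n$param) n$grad <- NULL  # free intermediates as we go
  }
  invisible(out)
}

# Collect every parameter tensor in a (nested) module list.
collect_params <- function(module) {
  out <- list()
  rec <- function(x) {
    if (inherits(x, "wt")) {
      if (x$param) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) rec(el)
    }
  }
  rec(module)
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

adamw_state <- function(params) {
  lapply(params, function(p)
    list(m = array(0, dim = dims_of(p$v)), v = array(0, dim = dims_of(p$v))))
}

adamw_step <- function(params, state, step, lr = 1e-4, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 1e-4) {
  b1t <- 1 - beta1^step; b2t <- 1 - beta2^step
  for (k in seq_along(params)) {
    p <- params[[k]]
    if (is.null(p$grad)) next
    g <- p$grad
    st <- state[[k]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    upd <- (st$m / b1t) / (sqrt(st$v / b2t) + eps)
    p$v <- p$v - lr * (upd + weight_decay * p$v)
    state[[k]] <- st
  }
  state
}
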