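# Finite-difference gradient checking for the autodiff engine.
#
# `gradcheck(make_loss, params)` builds the scalar loss from the given
# parameter tensors, backpropagates, and compares every parameter gradient
# against central differences.

ns <- asNamespace("wmcdetr")
tt <- ns$tt; tp <- ns$tp; val <- ns$val
bw <- ns$backward

gradcheck <- function(make_loss, params, eps = 1e-5, tol = 1e-4) {
  loss <- make_loss(params)
  for (p in params) p$grad <- NULL
  bw(loss)
  max_err <- 0
  for (p in params) {
    g <- p$grad
    if (is.null(g)) g <- array(0, dim = ns$dims_of(p$v))
    idx <- seq_len(length(p$v))
    if (length(idx) > 24) idx <- sort(sample(idx, 24))
    for (i in idx) {
      orig <- p$v[i]
      p$v[i] <- orig + eps
      up <- val(make_loss(params))
      p$v[i] <- orig - eps
      dn <- val(make_loss(params))
      p$v[i] <- orig
      num <- (up - dn) / (2 * eps)
      err <- abs(num - g[i]) / max(1, abs(num), abs(g[i]))
      max_err <- max(max_err, err)
    }
  }
  max_err
}

rnd <- function(...) array(rnorm(prod(c(...))), c(...))
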