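# Differentiable spatial operations backed by the compiled kernels.

check_fmap <- function(x, what = "feature map") {
  if (!is.numeric(x) || length(dim(x)) != 4L)
    stop(sprintf("%s must be a 4-D (batch, channel, row, col) array", what))
  invisible(x)
}

ag_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  if (dim(xv)[2L] != dim(wv)[2L])
    stop(sprintf("conv2d: expected %d input channels, got %d",
                 dim(wv)[2L], dim(xv)[2L]))
  out <- cpp_conv2d_fwd(xv, wv, bv, as.integer(stride), as.integer(pad))
  ag_op(out, list(x, w, b), function(g) {
    gr <- cpp_conv2d_bwd(xv, wv, g, as.integer(stride), as.integer(pad))
    list(gr$gx, gr$gw, gr$gb)
  })
}

ag_dwconv2d <- function(x, w, b, pad = 1L) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  if (dim(xv)[2L] != dim(wv)[1L])
    stop(sprintf("depthwise conv: expected %d channels, got %d",
                 dim(wv)[1L], dim(xv)[2L]))
  out <- cpp_dwconv2d_fwd(xv, wv, bv, as.integer(pad))
  ag_op(out, list(x, w, b), function(g) {
    gr <- cpp_dwconv2d_bwd(xv, wv, g, as.integer(pad))
    list(gr$gx, gr$gw, gr$gb)
  })
}

ag_maxpool2 <- function(x) {
  xv <- ag_value(x)
  r <- cpp_maxpool2_fwd(xv)
  ag_op(r$out, list(x), function(g) {
    list(cpp_maxpool2_bwd(g, r$arg, dim(xv)))
  })
}

ag_upsample2 <- function(x) {
  xv <- ag_value(x)
  out <- cpp_upsample2_fwd(xv)
  ag_op(out, list(x), function(g) {
    list(cpp_upsample2_bwd(g, dim(xv)))
  })
}

# Batch normalisation over (N,H,W) per channel.  `state` is an
# environment with $running_mean and $running_var; training mode uses
# batch statistics (biased variance for normalisation, unbiased for the
# running update), inference uses the stored running statistics.
ag_batchnorm2d <- function(x, gamma, beta, state, training = FALSE,
                           momentum = 0.1, eps = 1e-5) {
  xv <- ag_value(x); gv <- ag_value(gamma); bv <- ag_value(beta)
  d <- dim(xv)
  m <- d[1L] * d[3L] * d[4L]
  M <- aperm(xv, c(1L, 3L, 4L, 2L))
  dim(M) <- c(m, d[2L])
  if (training) {
    mu <- colMeans(M)
    xc <- sweep(M, 2L, mu, "-")
    va <- colMeans(xc * xc)
    if (m > 1L)
      state$running_var <- (1 - momentum) * state$running_var +
        momentum * va * m / (m - 1L)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
  } else {
    mu <- state$running_mean
    xc <- sweep(M, 2L, mu, "-")
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  out <- sweep(xhat, 2L, gv, "*")
  out <- sweep(out, 2L, bv, "+")
  dim(out) <- c(d[1L], d[3L], d[4L], d[2L])
  out <- aperm(out, c(1L, 4L, 2L, 3L))
  ag_op(out, list(x, gamma, beta), function(g) {
    g <- aperm(g, c(1L, 3L, 4L, 2L))
    dim(g) <- c(m, d[2L])
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2L, gv, "*")
    if (training) {
      dx <- sweep(
        dxhat - rep(colMeans(dxhat), each = m) -
          xhat * rep(colMeans(dxhat * xhat), each = m),
        2L, inv, "*")
    } else {
      dx <- sweep(dxhat, 2L, inv, "*")
    }
    dim(dx) <- c(d[1L], d[3L], d[4L], d[2L])
    list(aperm(dx, c(1L, 4L, 2L, 3L)), dgamma, dbeta)
  })
}
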