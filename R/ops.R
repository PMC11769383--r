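# Primitive differentiable operations on plain numeric arrays.
#
# Every op accepts either tensor nodes or plain arrays; with gradient
# recording off (the default) they compute on values only.  Feature maps
# are (batch, channel, row, col); token stacks are (batch, token, channel).

#' @useDynLib afnnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis dnorm pnorm rnorm runif qnorm
NULL

sigmoid <- function(x) stats::plogis(x)

gelu_val <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av + bv, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, s) {
  av <- ag_value(a)
  ag_op(av * s, list(a), function(g) list(g * s))
}

ag_relu <- function(a) {
  av <- ag_value(a)
  out <- av
  out[out < 0] <- 0
  ag_op(out, list(a), function(g) {
    g[av < 0] <- 0
    list(g)
  })
}

ag_gelu <- function(a) {
  av <- ag_value(a)
  Phi <- stats::pnorm(av)
  ag_op(av * Phi, list(a), function(g)
    list(g * (Phi + av * stats::dnorm(av))))
}

ag_sigmoid <- function(a) {
  av <- ag_value(a)
  s <- sigmoid(av)
  ag_op(s, list(a), function(g) list(g * s * (1 - s)))
}

# channel concatenation of two (N,C,H,W) maps, first argument first
ag_concat_ch <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  da <- dim(av); db <- dim(bv)
  if (!all(da[c(1L, 3L, 4L)] == db[c(1L, 3L, 4L)]))
    stop(sprintf(
      "concat: batch/spatial dims differ: (%s) vs (%s)",
      paste(da, collapse = ","), paste(db, collapse = ",")))
  ca <- da[2L]
  out <- array(0, c(da[1L], ca + db[2L], da[3L], da[4L]))
  out[, seq_len(ca), , ] <- av
  out[, ca + seq_len(db[2L]), , ] <- bv
  ag_op(out, list(a, b), function(g) {
    list(g[, seq_len(ca), , , drop = FALSE],
         g[, ca + seq_len(db[2L]), , , drop = FALSE])
  })
}

# (N,C,H,W) -> (N, H*W, C) token stack (row-major token order: row fastest)
ag_tokens <- function(a) {
  av <- ag_value(a)
  d <- dim(av)
  out <- aperm(av, c(1L, 3L, 4L, 2L))
  dim(out) <- c(d[1L], d[3L] * d[4L], d[2L])
  ag_op(out, list(a), function(g) {
    dim(g) <- c(d[1L], d[3L], d[4L], d[2L])
    list(aperm(g, c(1L, 4L, 2L, 3L)))
  })
}

# (N, H*W, C) -> (N,C,H,W)
ag_untokens <- function(a, H, W) {
  av <- ag_value(a)
  d <- dim(av)
  v <- av
  dim(v) <- c(d[1L], H, W, d[3L])
  out <- aperm(v, c(1L, 4L, 2L, 3L))
  ag_op(out, list(a), function(g) {
    g <- aperm(g, c(1L, 3L, 4L, 2L))
    dim(g) <- d
    list(g)
  })
}

# dense layer over the channel dimension of a (N,T,C) stack
ag_linear <- function(a, w, b) {
  av <- ag_value(a); wv <- ag_value(w); bv <- ag_value(b)
  d <- dim(av)
  M <- av
  dim(M) <- c(d[1L] * d[2L], d[3L])
  out <- M %*% wv
  out <- out + rep(bv, each = nrow(out))
  dim(out) <- c(d[1L], d[2L], ncol(wv))
  ag_op(out, list(a, w, b), function(g) {
    dim(g) <- c(d[1L] * d[2L], ncol(wv))
    ga <- g %*% t(wv)
    dim(ga) <- d
    list(ga, crossprod(M, g), colSums(g))
  })
}

# layer normalisation over the channel dimension of (N,T,C)
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- ag_value(a); gv <- ag_value(gamma); bv <- ag_value(beta)
  d <- dim(av)
  M <- av
  dim(M) <- c(d[1L] * d[2L], d[3L])
  mu <- rowMeans(M)
  xc <- M - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2L, gv, "*")
  out <- sweep(out, 2L, bv, "+")
  dim(out) <- d
  ag_op(out, list(a, gamma, beta), function(g) {
    dim(g) <- c(d[1L] * d[2L], d[3L])
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2L, gv, "*")
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# (N,T,C) -> (N*heads, T, C/heads)
ag_split_heads <- function(a, heads) {
  av <- ag_value(a)
  d <- dim(av)
  dh <- d[3L] %/% heads
  v <- av
  dim(v) <- c(d[1L], d[2L], dh, heads)
  out <- aperm(v, c(1L, 4L, 2L, 3L))
  dim(out) <- c(d[1L] * heads, d[2L], dh)
  ag_op(out, list(a), function(g) {
    dim(g) <- c(d[1L], heads, d[2L], dh)
    g <- aperm(g, c(1L, 3L, 4L, 2L))
    dim(g) <- d
    list(g)
  })
}

# (N*heads, T, C/heads) -> (N,T,C)
ag_merge_heads <- function(a, heads) {
  av <- ag_value(a)
  d <- dim(av)
  n <- d[1L] %/% heads
  v <- av
  dim(v) <- c(n, heads, d[2L], d[3L])
  out <- aperm(v, c(1L, 3L, 4L, 2L))
  dim(out) <- c(n, d[2L], d[3L] * heads)
  ag_op(out, list(a), function(g) {
    dim(g) <- c(n, d[2L], d[3L], heads)
    g <- aperm(g, c(1L, 4L, 2L, 3L))
    dim(g) <- d
    list(g)
  })
}

ag_transpose12 <- function(a) {
  av <- ag_value(a)
  out <- aperm(av, c(1L, 3L, 2L))
  ag_op(out, list(a), function(g) list(aperm(g, c(1L, 3L, 2L))))
}

bmm_slice <- function(x, i, nr, nc) {
  s <- x[i, , ]
  if (is.null(dim(s))) dim(s) <- c(nr, nc)
  s
}

# batched matrix multiply: (B,T,K) x (B,K,S) -> (B,T,S)
ag_bmm <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  da <- dim(av); db <- dim(bv)
  out <- array(0, c(da[1L], da[2L], db[3L]))
  for (i in seq_len(da[1L]))
    out[i, , ] <- bmm_slice(av, i, da[2L], da[3L]) %*%
      bmm_slice(bv, i, db[2L], db[3L])
  ag_op(out, list(a, b), function(g) {
    ga <- array(0, da)
    gb <- array(0, db)
    for (i in seq_len(da[1L])) {
      gi <- bmm_slice(g, i, da[2L], db[3L])
      bi <- bmm_slice(bv, i, db[2L], db[3L])
      ai <- bmm_slice(av, i, da[2L], da[3L])
      ga[i, , ] <- gi %*% t(bi)
      gb[i, , ] <- crossprod(ai, gi)
    }
    list(ga, gb)
  })
}

# softmax over the last dimension of (B,T,S)
ag_softmax <- function(a) {
  av <- ag_value(a)
  d <- dim(av)
  M <- av
  dim(M) <- c(d[1L] * d[2L], d[3L])
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  E <- exp(M - mx)
  s <- E / rowSums(E)
  out <- s
  dim(out) <- d
  ag_op(out, list(a), function(g) {
    dim(g) <- c(d[1L] * d[2L], d[3L])
    dx <- s * (g - rowSums(g * s))
    dim(dx) <- d
    list(dx)
  })
}
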