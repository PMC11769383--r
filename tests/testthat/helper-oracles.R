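# Independent reference implementations used as oracles: direct
# per-pixel loops, brute-force minima, closed-form counts.  None of
# them share code with the package's compute path.

# plain quadruple-loop 2-D convolution on (N,C,H,W)
naive_conv <- function(x, w, b, stride = 1, pad = 1) {
  d <- dim(x); wd <- dim(w)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Co <- wd[1]; kh <- wd[3]; kw <- wd[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  out <- array(0, c(N, Co, Ho, Wo))
  for (n in 1:N) for (co in 1:Co) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- b[co]
    for (ci in 1:C) for (ki in 1:kh) for (kj in 1:kw) {
      hi <- (ho - 1) * stride - pad + ki
      wi <- (wo - 1) * stride - pad + kj
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + w[co, ci, ki, kj] * x[n, ci, hi, wi]
    }
    out[n, co, ho, wo] <- acc
  }
  out
}

# depthwise variant (weights (C,kh,kw)), stride 1
naive_dwconv <- function(x, w, b, pad = 1) {
  d <- dim(x); wd <- dim(w)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  kh <- wd[2]; kw <- wd[3]
  out <- array(0, c(N, C, H + 2 * pad - kh + 1, W + 2 * pad - kw + 1))
  for (n in 1:N) for (c in 1:C)
    for (ho in seq_len(dim(out)[3])) for (wo in seq_len(dim(out)[4])) {
      acc <- b[c]
      for (ki in 1:kh) for (kj in 1:kw) {
        hi <- ho - 1 - pad + ki
        wi <- wo - 1 - pad + kj
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc <- acc + w[c, ki, kj] * x[n, c, hi, wi]
      }
      out[n, c, ho, wo] <- acc
    }
  out
}

sigm <- function(x) 1 / (1 + exp(-x))
gelu_ref <- function(x) x * pnorm(x)

layer_w <- function(l) l$params$w$value
layer_b <- function(l) l$params$b$value

# definitional scalar references for the bespoke blocks ---------------

wfiu_oracle <- function(x, blk) {
  x1 <- sigm(naive_conv(x, layer_w(blk$conv_w1), layer_b(blk$conv_w1)))
  x2 <- gelu_ref(naive_conv(x, layer_w(blk$conv_w2), layer_b(blk$conv_w2)))
  x1 * x2
}

feu_oracle <- function(x, x3, blk) {
  x4 <- gelu_ref(naive_conv(x3, layer_w(blk$conv_w3), layer_b(blk$conv_w3)))
  x5 <- naive_conv(x, layer_w(blk$conv_w4), layer_b(blk$conv_w4), pad = 0)
  x4 + x5
}

# inference-mode batch norm with identity running statistics
bn_identity_oracle <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  for (c in seq_len(d[2]))
    x[, c, , ] <- x[, c, , ] / sqrt(1 + eps) * gamma[c] + beta[c]
  x
}

dscom_oracle <- function(x, blk) {
  s1 <- naive_conv(x, layer_w(blk$conv1), layer_b(blk$conv1))
  s1 <- naive_dwconv(s1, layer_w(blk$dw1), layer_b(blk$dw1))
  s1 <- pmax(bn_identity_oracle(s1, blk$bn1$params$gamma$value,
                                blk$bn1$params$beta$value), 0)
  s2 <- naive_conv(s1, layer_w(blk$conv2), layer_b(blk$conv2))
  s2 <- naive_dwconv(s2, layer_w(blk$dw2), layer_b(blk$dw2))
  pmax(bn_identity_oracle(s2, blk$bn2$params$gamma$value,
                          blk$bn2$params$beta$value), 0)
}

# brute-force boundary / distance oracles ------------------------------

brute_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    if (m[i, j] == 0) next
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > H || nb[2] < 1 || nb[2] > W) next
      if (m[nb[1], nb[2]] != m[i, j]) { out[i, j] <- 1; break }
    }
  }
  out
}

brute_distance <- function(boundary) {
  H <- nrow(boundary); W <- ncol(boundary)
  idx <- which(boundary != 0, arr.ind = TRUE)
  out <- matrix(0, H, W)
  if (nrow(idx) == 0) return(out)
  for (i in 1:H) for (j in 1:W)
    out[i, j] <- sqrt(min((i - idx[, 1])^2 + (j - idx[, 2])^2))
  out
}

# scalar forward-difference gradient magnitude (loop form)
loop_grad_mag <- function(p) {
  H <- nrow(p); W <- ncol(p)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    gx <- if (j < W) p[i, j + 1] - p[i, j] else 0
    gy <- if (i < H) p[i + 1, j] - p[i, j] else 0
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# closed-form parameter count for an afn_config, summed layer by layer
closed_form_params <- function(cfg) {
  k2 <- cfg$dscom_kernel^2
  kd2 <- cfg$dscom_dw_kernel^2
  kw2 <- cfg$wfeu_kernel^2
  w <- cfg$widths
  conv_p <- function(k2_, cin, cout) k2_ * cin * cout + cout
  dscom_p <- function(cin, cout)
    conv_p(k2, cin, cout) + (kd2 * cout + cout) + 2 * cout +
    conv_p(k2, cout, cout) + (kd2 * cout + cout) + 2 * cout
  wfeu_p <- function(enc, dec, out)
    conv_p(kw2, enc + dec, out) * 2 + conv_p(kw2, out, out) +
    conv_p(1, enc + dec, out)
  trblock_p <- function(C, r) {
    2 * C + 4 * (C^2 + C) + 2 * C + (C * r * C + r * C) + (r * C * C + C)
  }
  total <- dscom_p(cfg$in_channels, w[1]) + dscom_p(w[1], w[2])
  for (s in 1:3) {
    cin <- w[s + 1]; cout <- w[s + 2]
    total <- total + conv_p(9, cin, cout) +
      cfg$depths[s] * trblock_p(cout, cfg$mlp_ratio)
  }
  for (lvl in 4:1) {
    total <- total + conv_p(9, w[lvl + 1], w[lvl]) +      # upsample conv
      wfeu_p(w[lvl], w[lvl], w[lvl]) +                    # skip fusion
      conv_p(9, w[lvl], w[lvl]) + 2 * w[lvl]              # refinement
  }
  total + conv_p(1, w[1], cfg$head_channels)
}

# set every parameter of a nested block list to a constant
zero_params <- function(blocks, value = 0) {
  for (p in afnnet:::collect_params(blocks)) p$value[] <- value
  invisible(blocks)
}

rand_fmap <- function(n, c, h, w) array(rnorm(n * c * h * w), c(n, c, h, w))
rand_mask <- function(n, h, w, p = 0.3)
  array(rbinom(n * h * w, 1, p), c(n, 1, h, w))
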