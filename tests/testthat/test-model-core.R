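# WFIU / FEU / WFEU and DSCOM blocks against per-pixel scalar oracles,
# plus assembly, parameter-count and checkpoint contracts.

test_that("wfiu matches the scalar oracle and its closed-form limits", {
  set.seed(201)
  blk <- wfeu_block(2, 2, 4)   # concatenated input = 4 channels
  x <- rand_fmap(1, 4, 5, 5)

  out <- wfiu_forward(x, blk)
  expect_equal(dim(out), c(1L, 4L, 5L, 5L))
  expect_lt(max(abs(out - wfiu_oracle(x, blk))), 1e-6)

  # zero kernels and biases: GELU(0) = 0 forces the product to zero
  zero_params(blk)
  expect_equal(max(abs(wfiu_forward(x, blk))), 0)

  # saturated sigmoid branch (W1 = 0, b1 = +20): output = GELU branch
  set.seed(202)
  blk2 <- wfeu_block(2, 2, 4)
  blk2$conv_w1$params$w$value[] <- 0
  blk2$conv_w1$params$b$value[] <- 20
  w2 <- layer_w(blk2$conv_w2); b2 <- layer_b(blk2$conv_w2)
  gelu_branch <- gelu_ref(naive_conv(x, w2, b2))
  expect_lt(max(abs(wfiu_forward(x, blk2) - gelu_branch)), 1e-6)
})

test_that("wfiu rejects a channel-count mismatch, naming both counts", {
  blk <- wfeu_block(2, 2, 4)
  expect_error(wfiu_forward(rand_fmap(1, 3, 5, 5), blk),
               "expected 4 input channels, got 3")
})

test_that("feu matches the scalar oracle and its closed-form limits", {
  set.seed(203)
  blk <- wfeu_block(3, 3, 5)
  x <- rand_fmap(2, 6, 4, 4)
  x3 <- rand_fmap(2, 5, 4, 4)
  expect_lt(max(abs(feu_forward(x, x3, blk) - feu_oracle(x, x3, blk))),
            1e-6)

  # all parameters zero: output zero
  zero_params(blk)
  expect_equal(max(abs(feu_forward(x, x3, blk))), 0)

  # only the alignment-branch bias set: constant map per channel
  cvals <- c(0.3, -1.2, 0.5, 2, -0.1)
  blk$conv_w4$params$b$value <- cvals
  out <- feu_forward(x, x3, blk)
  for (ch in 1:5)
    expect_equal(max(abs(out[, ch, , ] - cvals[ch])), 0)

  expect_error(feu_forward(x, rand_fmap(2, 5, 3, 4), blk),
               "spatial/batch mismatch")
})

test_that("wfeu is exactly the composition concat -> wfiu -> feu", {
  set.seed(204)
  blk <- wfeu_block(3, 4, 6)
  enc <- rand_fmap(2, 3, 6, 6)
  dec <- rand_fmap(2, 4, 6, 6)
  fused <- wfeu_forward(enc, dec, blk)
  expect_equal(dim(fused), c(2L, 6L, 6L, 6L))

  cc <- array(0, c(2, 7, 6, 6))
  cc[, 1:3, , ] <- enc   # encoder channels first
  cc[, 4:7, , ] <- dec
  expect_identical(fused, feu_forward(cc, wfiu_forward(cc, blk), blk))

  zero_params(blk)
  expect_equal(max(abs(wfeu_forward(enc, dec, blk))), 0)
  expect_error(wfeu_forward(enc, rand_fmap(2, 4, 5, 6), blk),
               "batch/spatial dims differ")
})

test_that("dscom matches the scalar oracle and keeps its contracts", {
  set.seed(205)
  blk <- dscom_block(2, 3)
  x <- rand_fmap(1, 2, 6, 6)
  expect_lt(max(abs(dscom_forward(x, blk) - dscom_oracle(x, blk))), 1e-5)

  # shape contract Cin -> Cout at preserved spatial size
  blk2 <- dscom_block(3, 16)
  out <- dscom_forward(rand_fmap(1, 3, 64, 64), blk2)
  expect_equal(dim(out), c(1L, 16L, 64L, 64L))
  expect_true(all(out >= 0))        # terminal ReLU
  expect_true(all(is.finite(out)))

  zero_params(blk)
  expect_equal(max(abs(dscom_forward(x, blk))), 0)
  expect_error(dscom_forward(rand_fmap(1, 5, 6, 6), blk),
               "expected 2 input channels, got 5")
})

test_that("blocks preserve spatial dimensions on randomized shapes", {
  set.seed(206)
  for (rep in 1:5) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    ce <- sample(1:4, 1); cd <- sample(1:4, 1); co <- sample(1:4, 1)
    blk <- wfeu_block(ce, cd, co)
    out <- wfeu_forward(rand_fmap(1, ce, h, w), rand_fmap(1, cd, h, w), blk)
    expect_equal(dim(out), c(1L, co, h, w))
    dblk <- dscom_block(ce, co)
    expect_equal(dim(dscom_forward(rand_fmap(1, ce, h, w), dblk)),
                 c(1L, co, h, w))
  }
})

test_that("model forward obeys shape contracts and rejects bad sizes", {
  set.seed(207)
  m <- build_afn_net(afn_config_tiny())
  x <- rand_fmap(2, 3, 32, 32)
  out <- afn_forward(m, x)
  expect_equal(dim(out), c(2L, 1L, 32L, 32L))
  expect_true(all(is.finite(out)))
  # minimum size: one pixel at the bottleneck after four 2x reductions
  expect_equal(dim(afn_forward(m, rand_fmap(1, 3, 16, 16))),
               c(1L, 1L, 16L, 16L))
  expect_error(afn_forward(m, rand_fmap(1, 3, 24, 24)),
               "not divisible by 16")
  expect_error(afn_forward(m, rand_fmap(1, 4, 32, 32)),
               "expected 3 input channels")
})

test_that("model output is deterministic in inference mode", {
  m <- build_afn_net(afn_config_tiny(seed = 9L))
  m2 <- build_afn_net(afn_config_tiny(seed = 9L))
  set.seed(208)
  x <- rand_fmap(1, 3, 32, 32)
  expect_identical(afn_forward(m, x), afn_forward(m, x))
  expect_identical(afn_forward(m, x), afn_forward(m2, x))
})

test_that("count_parameters matches the symbolic per-layer sum", {
  expect_equal(count_parameters(list()), 0L)
  single <- list(conv = afnnet:::new_conv(3, 16, 3))
  expect_equal(count_parameters(single), 3 * 16 * 9 + 16)

  cfg <- afn_config_tiny()
  m <- build_afn_net(cfg)
  expect_equal(count_parameters(m), closed_form_params(cfg))

  cfg2 <- afn_config(widths = c(8, 16, 32, 32, 64), depths = c(1, 2, 2))
  expect_equal(count_parameters(build_afn_net(cfg2)),
               closed_form_params(cfg2))
})

test_that("end-to-end forward pass is differentiable (input gradient)", {
  set.seed(209)
  m <- build_afn_net(afn_config_tiny())
  x <- rand_fmap(1, 3, 16, 16)
  xn <- ag_leaf(x)
  out <- with_grad(afn_forward(m, xn))
  ag_backward(out, grad = array(1, dim(ag_value(out))))
  f <- function(v) sum(afn_forward(m, v))
  for (i in sample(length(x), 4)) {
    xp <- x; xp[i] <- x[i] + 1e-5
    xm <- x; xm[i] <- x[i] - 1e-5
    fdg <- (f(xp) - f(xm)) / 2e-5
    expect_lt(abs(xn$grad[i] - fdg) / max(abs(fdg), 1e-8), 1e-3)
  }
})

test_that("checkpoints round-trip parameters and catch config drift", {
  set.seed(210)
  m <- build_afn_net(afn_config_tiny(seed = 3L))
  x <- rand_fmap(1, 3, 16, 16)
  before <- afn_forward(m, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, extra = list(note = "fixture"))
  ck <- load_checkpoint(path)
  expect_identical(afn_forward(ck$model, x), before)
  expect_equal(ck$extra$note, "fixture")

  # tamper with a stored parameter shape -> shape error
  obj <- readRDS(path)
  obj$params[["head.w"]] <- array(0, c(2, 4, 1, 1))
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "mismatched shape")

  # drop a key -> divergent-keys error
  obj$params[["head.w"]] <- NULL
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "divergent keys")
})
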