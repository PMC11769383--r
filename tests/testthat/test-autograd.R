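# Gradient correctness of the primitive differentiable operations,
# checked against central finite differences.

fd_grad <- function(f, a, eps = 1e-6) {
  g <- a * 0
  for (i in seq_along(a)) {
    ap <- a; ap[i] <- a[i] + eps
    am <- a; am[i] <- a[i] - eps
    g[i] <- (f(ap) - f(am)) / (2 * eps)
  }
  g
}

grad_of <- function(f, x) {
  n <- ag_leaf(x)
  out <- with_grad(f(n))
  ag_backward(out, grad = array(1, dim(ag_value(out))))
  n$grad
}

test_that("elementwise and activation ops match finite differences", {
  set.seed(101)
  x <- rand_fmap(2, 3, 4, 5)
  for (op in list(afnnet:::ag_relu, afnnet:::ag_gelu, afnnet:::ag_sigmoid)) {
    ga <- grad_of(op, x)
    gn <- fd_grad(function(v) sum(ag_value(op(v))), x)
    expect_lt(max(abs(ga - gn)), 1e-6)
  }
  y <- rand_fmap(2, 3, 4, 5)
  ga <- grad_of(function(n) afnnet:::ag_mul(n, y), x)
  expect_lt(max(abs(ga - y)), 1e-12)
})

test_that("token, linear, layernorm and softmax ops match finite differences", {
  set.seed(102)
  t3 <- array(rnorm(2 * 6 * 4), c(2, 6, 4))
  w <- matrix(rnorm(4 * 5), 4, 5); b <- rnorm(5)
  ga <- grad_of(function(n) afnnet:::ag_linear(n, w, b), t3)
  gn <- fd_grad(function(v) sum(ag_value(afnnet:::ag_linear(v, w, b))), t3)
  expect_lt(max(abs(ga - gn)), 1e-6)

  gm <- rnorm(4); bt <- rnorm(4)
  ga <- grad_of(function(n) afnnet:::ag_layernorm(n, gm, bt), t3)
  gn <- fd_grad(function(v)
    sum(ag_value(afnnet:::ag_layernorm(v, gm, bt))), t3)
  expect_lt(max(abs(ga - gn)), 1e-5)

  # softmax needs a non-uniform downstream weighting to exercise the
  # Jacobian, so weight the output by a fixed random field
  wfield <- array(rnorm(2 * 6 * 4), c(2, 6, 4))
  f <- function(n) afnnet:::ag_mul(afnnet:::ag_softmax(n), wfield)
  ga <- grad_of(f, t3)
  gn <- fd_grad(function(v) sum(ag_value(f(v))), t3)
  expect_lt(max(abs(ga - gn)), 1e-6)
})

test_that("attention composition (split/bmm/softmax/merge) differentiates", {
  set.seed(103)
  t3 <- array(rnorm(1 * 6 * 8), c(1, 6, 8))
  wfield <- array(rnorm(1 * 6 * 8), c(1, 6, 8))
  att <- function(n) {
    q <- afnnet:::ag_split_heads(n, 2L)
    s <- afnnet:::ag_scale(
      afnnet:::ag_bmm(q, afnnet:::ag_transpose12(q)), 1 / 2)
    o <- afnnet:::ag_merge_heads(
      afnnet:::ag_bmm(afnnet:::ag_softmax(s), q), 2L)
    afnnet:::ag_mul(o, wfield)
  }
  ga <- grad_of(att, t3)
  gn <- fd_grad(function(v) sum(ag_value(att(v))), t3)
  expect_lt(max(abs(ga - gn)), 1e-6)
})

test_that("conv, depthwise, pool and upsample ops match finite differences", {
  set.seed(104)
  x <- rand_fmap(2, 3, 6, 6)
  w <- array(rnorm(4 * 3 * 3 * 3), c(4, 3, 3, 3)); b <- rnorm(4)
  ga <- grad_of(function(n) afnnet:::ag_conv2d(n, w, b), x)
  gn <- fd_grad(function(v) sum(afnnet:::cpp_conv2d_fwd(v, w, b, 1L, 1L)), x)
  expect_lt(max(abs(ga - gn)), 1e-6)

  wd <- array(rnorm(3 * 3 * 3), c(3, 3, 3)); bd <- rnorm(3)
  ga <- grad_of(function(n) afnnet:::ag_dwconv2d(n, wd, bd), x)
  gn <- fd_grad(function(v) sum(afnnet:::cpp_dwconv2d_fwd(v, wd, bd, 1L)), x)
  expect_lt(max(abs(ga - gn)), 1e-6)

  ga <- grad_of(afnnet:::ag_maxpool2, x)
  gn <- fd_grad(function(v) sum(afnnet:::cpp_maxpool2_fwd(v)$out), x)
  expect_lt(max(abs(ga - gn)), 1e-6)

  ga <- grad_of(afnnet:::ag_upsample2, x)
  gn <- fd_grad(function(v) sum(afnnet:::cpp_upsample2_fwd(v)), x)
  expect_lt(max(abs(ga - gn)), 1e-6)
})

test_that("batch norm differentiates in both training and eval mode", {
  set.seed(105)
  x <- rand_fmap(3, 2, 4, 4)
  gm <- ag_leaf(rnorm(2, 1, 0.1)); bt <- ag_leaf(rnorm(2, 0, 0.1))
  for (mode in c(TRUE, FALSE)) {
    st <- new.env()
    st$running_mean <- rnorm(2, 0, 0.2)
    st$running_var <- runif(2, 0.5, 2)
    st0 <- list(m = st$running_mean, v = st$running_var)
    n <- ag_leaf(x)
    out <- with_grad(afnnet:::ag_batchnorm2d(n, gm, bt, st, training = mode))
    ag_backward(out, grad = array(1, dim(x)))
    fd_once <- function(v) {
      s2 <- new.env()
      s2$running_mean <- st0$m; s2$running_var <- st0$v
      sum(afnnet:::ag_batchnorm2d(v, gm$value, bt$value, s2,
                                  training = mode))
    }
    gn <- fd_grad(fd_once, x, eps = 1e-5)
    expect_lt(max(abs(n$grad - gn)), 1e-5)
  }
})

test_that("gradient-scheme shift operators satisfy the adjoint identity", {
  set.seed(106)
  for (scheme in c("forward", "central", "sobel")) {
    taps <- afnnet:::grad_taps(scheme)
    for (tp in list(taps$gx, taps$gy)) {
      v <- matrix(rnorm(63), 7, 9)
      u <- matrix(rnorm(63), 7, 9)
      lhs <- sum(afnnet:::apply_taps(v, tp) * u)
      rhs <- sum(v * afnnet:::apply_taps_adj(u, tp))
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("gradients accumulate over reuse and zero_grad clears leaves", {
  x <- ag_leaf(array(2, c(1, 1, 2, 2)))
  out <- with_grad(afnnet:::ag_add(x, x))
  ag_backward(out, grad = array(1, c(1, 1, 2, 2)))
  expect_equal(as.numeric(x$grad), rep(2, 4))
  ag_zero_grad(list(x))
  expect_null(x$grad)
})
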