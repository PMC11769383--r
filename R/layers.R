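# Layer constructors.  A layer is an environment with $params (named
# list of leaf tensors), an optional $state environment (batch-norm
# running statistics) and a $kind tag used for parameter collection.

new_layer <- function(kind, params, state = NULL) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- params
  e$state <- state
  class(e) <- "ag_layer"
  e
}

# Kaiming-uniform initialisation with the conv-layer default slope
# (a = sqrt(5)), i.e. U(-b, b) with b = sqrt(1 / fan_in); the milder
# scale keeps the multiplicative WFIU gates out of saturation at init
kaiming_uniform <- function(dims, fan_in) {
  b <- sqrt(1 / fan_in)
  array(runif(prod(dims), -b, b), dims)
}

# normal(0, sd) truncated at +/- 2 sd (transformer weights)
trunc_normal <- function(dims, sd = 0.02) {
  lo <- pnorm(-2)
  array(qnorm(runif(prod(dims), lo, 1 - lo)) * sd, dims)
}

new_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  l <- new_layer("conv", list(
    w = ag_leaf(kaiming_uniform(c(cout, cin, k, k), cin * k * k)),
    b = ag_leaf(numeric(cout))))
  l$stride <- as.integer(stride)
  l$pad <- as.integer(pad)
  l
}

conv_fwd <- function(l, x) ag_conv2d(x, l$params$w, l$params$b, l$stride, l$pad)

new_dwconv <- function(ch, k = 3L, pad = (k - 1L) %/% 2L) {
  l <- new_layer("dwconv", list(
    w = ag_leaf(kaiming_uniform(c(ch, k, k), k * k)),
    b = ag_leaf(numeric(ch))))
  l$pad <- as.integer(pad)
  l
}

dwconv_fwd <- function(l, x) ag_dwconv2d(x, l$params$w, l$params$b, l$pad)

new_bn <- function(ch) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(ch)
  st$running_var <- rep(1, ch)
  new_layer("bn", list(gamma = ag_leaf(rep(1, ch)),
                       beta = ag_leaf(numeric(ch))), state = st)
}

bn_fwd <- function(l, x, training = FALSE)
  ag_batchnorm2d(x, l$params$gamma, l$params$beta, l$state, training)

new_linear <- function(cin, cout) {
  new_layer("linear", list(w = ag_leaf(trunc_normal(c(cin, cout))),
                           b = ag_leaf(numeric(cout))))
}

linear_fwd <- function(l, x) ag_linear(x, l$params$w, l$params$b)

new_ln <- function(ch) {
  new_layer("ln", list(gamma = ag_leaf(rep(1, ch)),
                       beta = ag_leaf(numeric(ch))))
}

ln_fwd <- function(l, x) ag_layernorm(x, l$params$gamma, l$params$beta)

is_layer <- function(x) inherits(x, "ag_layer")

# walk a nested block list and return the leaf parameter tensors named
# "enc1.conv1.w", "tr3.block1.attn_q.w", ...
collect_params <- function(blocks, prefix = NULL) {
  out <- list()
  if (is_layer(blocks)) {
    for (nm in names(blocks$params))
      out[[paste(c(prefix, nm), collapse = ".")]] <- blocks$params[[nm]]
    return(out)
  }
  for (nm in names(blocks))
    out <- c(out, collect_params(blocks[[nm]], c(prefix, nm)))
  out
}

# batch-norm state environments, named like their layers
collect_states <- function(blocks, prefix = NULL) {
  out <- list()
  if (is_layer(blocks)) {
    if (!is.null(blocks$state))
      out[[paste(prefix, collapse = ".")]] <- blocks$state
    return(out)
  }
  for (nm in names(blocks))
    out <- c(out, collect_states(blocks[[nm]], c(prefix, nm)))
  out
}
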