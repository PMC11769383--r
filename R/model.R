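# Network assembly: transformer stages, the full five-level
# encoder-decoder, parameter counting and checkpoints.

# one pre-norm transformer block (MHSA + MLP, both with residuals)
transformer_block <- function(ch, heads, mlp_ratio) {
  list(ln1 = new_ln(ch),
       attn_q = new_linear(ch, ch),
       attn_k = new_linear(ch, ch),
       attn_v = new_linear(ch, ch),
       attn_o = new_linear(ch, ch),
       ln2 = new_ln(ch),
       mlp1 = new_linear(ch, ch * mlp_ratio),
       mlp2 = new_linear(ch * mlp_ratio, ch))
}

transformer_stage <- function(ch, depth, heads, mlp_ratio) {
  blocks <- lapply(seq_len(depth), function(i)
    transformer_block(ch, heads, mlp_ratio))
  names(blocks) <- paste0("block", seq_len(depth))
  blocks
}

mhsa_fwd <- function(blk, t, heads) {
  h <- ln_fwd(blk$ln1, t)
  dh <- dim(ag_value(h))[3L] %/% heads
  q <- ag_split_heads(linear_fwd(blk$attn_q, h), heads)
  k <- ag_split_heads(linear_fwd(blk$attn_k, h), heads)
  v <- ag_split_heads(linear_fwd(blk$attn_v, h), heads)
  if (grad_on()) {
    scores <- ag_scale(ag_bmm(q, ag_transpose12(k)), 1 / sqrt(dh))
    o <- ag_merge_heads(ag_bmm(ag_softmax(scores), v), heads)
  } else {
    # inference: one head-slice at a time so the T x T score matrix of
    # high-resolution stages never materialises for the whole batch
    o <- attention_plain(ag_value(q), ag_value(k), ag_value(v), dh)
    o <- ag_merge_heads(o, heads)
  }
  ag_add(t, linear_fwd(blk$attn_o, o))
}

attention_plain <- function(q, k, v, dh) {
  d <- dim(q)
  out <- array(0, d)
  for (i in seq_len(d[1L])) {
    s <- tcrossprod(bmm_slice(q, i, d[2L], d[3L]),
                    bmm_slice(k, i, d[2L], d[3L])) / sqrt(dh)
    s <- exp(s - s[cbind(seq_len(d[2L]), max.col(s, ties.method = "first"))])
    out[i, , ] <- (s / rowSums(s)) %*% bmm_slice(v, i, d[2L], d[3L])
  }
  out
}

transformer_fwd <- function(stage, x, heads) {
  d <- dim(ag_value(x))
  t <- ag_tokens(x)
  for (blk in stage) {
    t <- mhsa_fwd(blk, t, heads)
    h <- ln_fwd(blk$ln2, t)
    t <- ag_add(t, linear_fwd(blk$mlp2, ag_gelu(linear_fwd(blk$mlp1, h))))
  }
  ag_untokens(t, d[3L], d[4L])
}

# conv -> batch norm -> ReLU (decoder refinement block)
conv_bn_block <- function(cin, cout, k = 3L) {
  list(conv = new_conv(cin, cout, k), bn = new_bn(cout))
}

conv_bn_fwd <- function(b, x, training = FALSE)
  ag_relu(bn_fwd(b$bn, conv_fwd(b$conv, x), training))

#' Build an AFN-Net model
#'
#' Assembles the five-level network: DSCOM encoder levels 1-2 with 2x2
#' max-pool downsampling, transformer stages 3-5 entered by stride-2
#' patch-embedding convolutions, a mirrored decoder (bilinear 2x
#' upsampling + 3x3 convolution) with a WFEU at each of the four skip
#' fusions and a conv-BN-ReLU refinement per decoder level, and a 1x1
#' convolution head emitting one logit channel at input resolution.
#' Parameter initialisation is driven by `config$seed` (Kaiming-uniform
#' convolutions, truncated-normal transformer weights).
#'
#' @param config an [afn_config()].
#' @return an object of class `afn_net`.
#' @export
build_afn_net <- function(config) {
  stopifnot(inherits(config, "afn_config"))
  w <- config$widths
  with_seed(config$seed, {
    blocks <- list(
      enc1 = dscom_block(config$in_channels, w[1L], config$dscom_kernel,
                         config$dscom_dw_kernel),
      enc2 = dscom_block(w[1L], w[2L], config$dscom_kernel,
                         config$dscom_dw_kernel),
      pe3 = new_conv(w[2L], w[3L], 3L, stride = 2L),
      tr3 = transformer_stage(w[3L], config$depths[1L], config$heads,
                              config$mlp_ratio),
      pe4 = new_conv(w[3L], w[4L], 3L, stride = 2L),
      tr4 = transformer_stage(w[4L], config$depths[2L], config$heads,
                              config$mlp_ratio),
      pe5 = new_conv(w[4L], w[5L], 3L, stride = 2L),
      tr5 = transformer_stage(w[5L], config$depths[3L], config$heads,
                              config$mlp_ratio),
      up4 = new_conv(w[5L], w[4L], 3L),
      wfeu4 = wfeu_block(w[4L], w[4L], w[4L], config$wfeu_kernel),
      ref4 = conv_bn_block(w[4L], w[4L]),
      up3 = new_conv(w[4L], w[3L], 3L),
      wfeu3 = wfeu_block(w[3L], w[3L], w[3L], config$wfeu_kernel),
      ref3 = conv_bn_block(w[3L], w[3L]),
      up2 = new_conv(w[3L], w[2L], 3L),
      wfeu2 = wfeu_block(w[2L], w[2L], w[2L], config$wfeu_kernel),
      ref2 = conv_bn_block(w[2L], w[2L]),
      up1 = new_conv(w[2L], w[1L], 3L),
      wfeu1 = wfeu_block(w[1L], w[1L], w[1L], config$wfeu_kernel),
      ref1 = conv_bn_block(w[1L], w[1L]),
      head = new_conv(w[1L], config$head_channels, 1L, pad = 0L))
    structure(list(config = config, blocks = blocks), class = "afn_net")
  })
}

#' Forward pass through an AFN-Net
#'
#' @param model an `afn_net` from [build_afn_net()].
#' @param x input batch, a (batch, channel, row, col) array whose
#'   spatial size must be divisible by 16 (four 2x reductions).
#' @param training propagate training mode to batch-norm layers.
#' @return logits of shape (batch, 1, row, col); plain array unless
#'   gradient recording is on.
#' @export
afn_forward <- function(model, x, training = FALSE) {
  xv <- ag_value(x)
  check_fmap(xv, "model input")
  d <- dim(xv)
  if (d[2L] != model$config$in_channels)
    stop(sprintf("afn_forward: expected %d input channels, got %d",
                 model$config$in_channels, d[2L]))
  if (d[3L] %% 16L != 0L || d[4L] %% 16L != 0L)
    stop(sprintf(
      "afn_forward: spatial size %dx%d is not divisible by 16", d[3L], d[4L]))
  b <- model$blocks
  heads <- model$config$heads
  e1 <- dscom_forward(x, b$enc1, training)
  e2 <- dscom_forward(ag_maxpool2(e1), b$enc2, training)
  e3 <- transformer_fwd(b$tr3, conv_fwd(b$pe3, e2), heads)
  e4 <- transformer_fwd(b$tr4, conv_fwd(b$pe4, e3), heads)
  e5 <- transformer_fwd(b$tr5, conv_fwd(b$pe5, e4), heads)
  d4 <- conv_bn_fwd(b$ref4,
                    wfeu_forward(e4, conv_fwd(b$up4, ag_upsample2(e5)),
                                 b$wfeu4), training)
  d3 <- conv_bn_fwd(b$ref3,
                    wfeu_forward(e3, conv_fwd(b$up3, ag_upsample2(d4)),
                                 b$wfeu3), training)
  d2 <- conv_bn_fwd(b$ref2,
                    wfeu_forward(e2, conv_fwd(b$up2, ag_upsample2(d3)),
                                 b$wfeu2), training)
  d1 <- conv_bn_fwd(b$ref1,
                    wfeu_forward(e1, conv_fwd(b$up1, ag_upsample2(d2)),
                                 b$wfeu1), training)
  conv_fwd(b$head, d1)
}

#' Predict foreground probabilities
#'
#' Runs the network in inference mode and applies the sigmoid.
#'
#' @inheritParams afn_forward
#' @return array (batch, 1, row, col) of probabilities.
#' @export
afn_predict <- function(model, x) {
  old <- ag_grad_enabled(FALSE)
  on.exit(ag_grad_enabled(old))
  sigmoid(ag_value(afn_forward(model, x, training = FALSE)))
}

#' Count trainable parameters
#'
#' @param model an `afn_net` (or any nested block list).
#' @return total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  blocks <- if (inherits(model, "afn_net")) model$blocks else model
  ps <- collect_params(blocks)
  if (length(ps) == 0L) return(0L)
  sum(vapply(ps, function(p) length(p$value), numeric(1L)))
}

#' Save model parameters and configuration to a checkpoint file
#'
#' The checkpoint is a single serialised container keyed by hierarchical
#' block names, together with the `afn_config` used to build the model
#' and the batch-norm running statistics.
#'
#' @param model an `afn_net`.
#' @param path destination file.
#' @param extra optional named list stored alongside (e.g. normalisation
#'   statistics, training history).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  ps <- collect_params(model$blocks)
  st <- collect_states(model$blocks)
  obj <- list(
    config = model$config,
    params = lapply(ps, function(p) p$value),
    states = lapply(st, function(s)
      list(running_mean = s$running_mean, running_var = s$running_var)),
    extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the architecture from the stored configuration and verifies
#' that every stored array matches the shape of the corresponding
#' parameter.
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return list with elements `model` and `extra`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- build_afn_net(obj$config)
  ps <- collect_params(model$blocks)
  if (!setequal(names(ps), names(obj$params)))
    stop(sprintf(
      "checkpoint/config mismatch; divergent keys: %s",
      paste(union(setdiff(names(ps), names(obj$params)),
                  setdiff(names(obj$params), names(ps))), collapse = ", ")))
  for (nm in names(ps)) {
    stored <- obj$params[[nm]]
    if (!identical(dim_or_len(stored), dim_or_len(ps[[nm]]$value)))
      stop(sprintf("checkpoint parameter '%s' has mismatched shape", nm))
    ps[[nm]]$value <- stored
  }
  st <- collect_states(model$blocks)
  for (nm in names(st)) {
    st[[nm]]$running_mean <- obj$states[[nm]]$running_mean
    st[[nm]]$running_var <- obj$states[[nm]]$running_var
  }
  list(model = model, extra = obj$extra)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)
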