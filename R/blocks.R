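# The two bespoke convolutional blocks: the Weighted Feature Enhancement
# Unit (WFIU + FEU) used at every skip fusion, and the Double-Stage
# Channel Optimization Module used in the first two encoder levels.

#' Create a Weighted Feature Enhancement Unit
#'
#' The WFEU fuses an encoder and a decoder feature map.  The two maps
#' are channel-concatenated (encoder first) and passed through the
#' Weighted Feature Interaction Unit — a sigmoid-gated dynamic weight
#' map multiplied with a GELU branch — followed by the Feature
#' Enhancement Unit, which adds a GELU-enhanced branch to a 1x1
#' channel-alignment projection of the concatenated input.
#'
#' @param enc_channels,dec_channels channels of the encoder and decoder
#'   inputs.
#' @param out_channels channels of the fused output (the decoder-stage
#'   width).
#' @param kernel kernel size of the 3x3 branches (the alignment branch
#'   is always 1x1).
#' @return a `wfeu_block` holding the four convolutions W1-W4.
#' @export
wfeu_block <- function(enc_channels, dec_channels,
                       out_channels = dec_channels, kernel = 3L) {
  cc <- enc_channels + dec_channels
  b <- list(
    conv_w1 = new_conv(cc, out_channels, kernel),
    conv_w2 = new_conv(cc, out_channels, kernel),
    conv_w3 = new_conv(out_channels, out_channels, kernel),
    conv_w4 = new_conv(cc, out_channels, 1L, pad = 0L))
  attr(b, "in_channels") <- cc
  attr(b, "enc_channels") <- as.integer(enc_channels)
  attr(b, "dec_channels") <- as.integer(dec_channels)
  attr(b, "out_channels") <- as.integer(out_channels)
  class(b) <- "wfeu_block"
  b
}

#' Weighted Feature Interaction Unit forward pass
#'
#' Computes the interaction feature
#' `x3 = sigmoid(W1 * x + b1) . GELU(W2 * x + b2)`:
#' a dynamic weight map gating a nonlinearly transformed copy of the
#' input, elementwise.
#'
#' @param x input feature map (batch, channel, row, col); the channel
#'   count must match the block's configured (concatenated) input.
#' @param params a [wfeu_block()].
#' @return feature map with the block's output channel count, same
#'   spatial size.
#' @export
wfiu_forward <- function(x, params) {
  xv <- ag_value(x)
  check_fmap(xv)
  expected <- attr(params, "in_channels")
  if (dim(xv)[2L] != expected)
    stop(sprintf("wfiu_forward: expected %d input channels, got %d",
                 expected, dim(xv)[2L]))
  x1 <- ag_sigmoid(conv_fwd(params$conv_w1, x))
  x2 <- ag_gelu(conv_fwd(params$conv_w2, x))
  ag_mul(x1, x2)
}

#' Feature Enhancement Unit forward pass
#'
#' Computes `out = GELU(W3 * x3 + b3) + (W4 * x + b4)` where W4 is the
#' 1x1 convolution aligning the channels of the original input `x` with
#' the enhanced interaction feature.
#'
#' @param x the block input (pre-WFIU, concatenated encoder/decoder
#'   feature).
#' @param x3 the interaction feature produced by [wfiu_forward()].
#' @param params a [wfeu_block()].
#' @return the fused feature map.
#' @export
feu_forward <- function(x, x3, params) {
  xv <- ag_value(x); x3v <- ag_value(x3)
  check_fmap(xv); check_fmap(x3v)
  if (!all(dim(xv)[c(1L, 3L, 4L)] == dim(x3v)[c(1L, 3L, 4L)]))
    stop(sprintf(
      "feu_forward: spatial/batch mismatch between x (%s) and x3 (%s)",
      paste(dim(xv), collapse = "x"), paste(dim(x3v), collapse = "x")))
  x4 <- ag_gelu(conv_fwd(params$conv_w3, x3))
  x5 <- conv_fwd(params$conv_w4, x)
  ag_add(x4, x5)
}

#' Weighted Feature Enhancement Unit forward pass
#'
#' Channel-concatenates the encoder and decoder features (encoder
#' first), then applies [wfiu_forward()] and [feu_forward()].
#'
#' @param encoder_feat,decoder_feat feature maps sharing batch and
#'   spatial dimensions.
#' @param params a [wfeu_block()].
#' @return fused feature map at the block's output width.
#' @export
wfeu_forward <- function(encoder_feat, decoder_feat, params) {
  ev <- ag_value(encoder_feat); dv <- ag_value(decoder_feat)
  check_fmap(ev); check_fmap(dv)
  if (!all(dim(ev)[c(1L, 3L, 4L)] == dim(dv)[c(1L, 3L, 4L)]))
    stop(sprintf(
      "wfeu_forward: encoder (%s) and decoder (%s) batch/spatial dims differ",
      paste(dim(ev), collapse = "x"), paste(dim(dv), collapse = "x")))
  x <- ag_concat_ch(encoder_feat, decoder_feat)
  feu_forward(x, wfiu_forward(x, params), params)
}

#' Create a Double-Stage Channel Optimization Module
#'
#' Two repetitions of standard convolution -> depthwise convolution ->
#' batch normalisation -> ReLU.  The first stage maps `cin` to `cout`
#' channels; the second keeps `cout`.
#'
#' @param cin,cout input and output channel counts.
#' @param kernel standard-convolution kernel size.
#' @param dw_kernel depthwise kernel size.
#' @return a `dscom_block`.
#' @export
dscom_block <- function(cin, cout, kernel = 3L, dw_kernel = 3L) {
  b <- list(
    conv1 = new_conv(cin, cout, kernel),
    dw1 = new_dwconv(cout, dw_kernel),
    bn1 = new_bn(cout),
    conv2 = new_conv(cout, cout, kernel),
    dw2 = new_dwconv(cout, dw_kernel),
    bn2 = new_bn(cout))
  attr(b, "in_channels") <- as.integer(cin)
  attr(b, "out_channels") <- as.integer(cout)
  class(b) <- "dscom_block"
  b
}

#' DSCOM forward pass
#'
#' Stage 1: standard conv (Cin to Cout), depthwise conv, batch norm,
#' ReLU.  Stage 2 repeats the sequence at constant width.  Spatial size
#' is preserved; the terminal ReLU makes the output non-negative.
#'
#' @param x input feature map with the block's configured input
#'   channels.
#' @param params a [dscom_block()].
#' @param training use batch statistics (and update running statistics)
#'   in the batch-norm layers.
#' @return output feature map with `cout` channels.
#' @export
dscom_forward <- function(x, params, training = FALSE) {
  xv <- ag_value(x)
  check_fmap(xv)
  expected <- attr(params, "in_channels")
  if (dim(xv)[2L] != expected)
    stop(sprintf("dscom_forward: expected %d input channels, got %d",
                 expected, dim(xv)[2L]))
  z <- ag_relu(bn_fwd(params$bn1,
                      dwconv_fwd(params$dw1, conv_fwd(params$conv1, x)),
                      training))
  ag_relu(bn_fwd(params$bn2,
                 dwconv_fwd(params$dw2, conv_fwd(params$conv2, z)),
                 training))
}
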