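# Model and training configuration.

#' Architecture configuration for AFN-Net
#'
#' The network is a five-level encoder-decoder.  Levels 1-2 are
#' convolutional (DSCOM blocks in the encoder), levels 3-5 are
#' transformer stages entered through a stride-2 patch-embedding
#' convolution.  The decoder mirrors the encoder with bilinear 2x
#' upsampling + 3x3 convolution, fuses each skip connection with a WFEU,
#' and ends in a 1x1 convolution head emitting one logit channel.
#'
#' @param widths integer vector of 5 per-level channel widths.
#' @param in_channels input image channels (3 for RGB).
#' @param heads attention heads per transformer stage.
#' @param mlp_ratio transformer MLP expansion factor.
#' @param depths transformer blocks in stages 3, 4, 5.
#' @param wfeu_kernel kernel size of the WFEU 3x3 branches.
#' @param dscom_kernel standard-convolution kernel size in DSCOM.
#' @param dscom_dw_kernel depthwise kernel size in DSCOM.
#' @param seed seed used for parameter initialisation.
#' @return an object of class `afn_config`.
#' @export
afn_config <- function(widths = c(16L, 32L, 128L, 160L, 256L),
                       in_channels = 3L,
                       heads = 4L,
                       mlp_ratio = 4L,
                       depths = c(1L, 2L, 2L),
                       wfeu_kernel = 3L,
                       dscom_kernel = 3L,
                       dscom_dw_kernel = 3L,
                       seed = 42L) {
  widths <- as.integer(widths)
  if (length(widths) != 5L || any(widths <= 0L))
    stop("`widths` must be 5 strictly positive integers (one per level)")
  depths <- as.integer(depths)
  if (length(depths) != 3L || any(depths < 1L))
    stop("`depths` must give >= 1 transformer blocks for stages 3-5")
  for (i in 1:3)
    if (widths[i + 2L] %% heads != 0L)
      stop(sprintf("transformer width %d is not divisible by %d heads",
                   widths[i + 2L], heads))
  structure(
    list(widths = widths, in_channels = as.integer(in_channels),
         heads = as.integer(heads), mlp_ratio = as.integer(mlp_ratio),
         depths = depths, wfeu_kernel = as.integer(wfeu_kernel),
         dscom_kernel = as.integer(dscom_kernel),
         dscom_dw_kernel = as.integer(dscom_dw_kernel),
         head_channels = 1L, seed = as.integer(seed)),
    class = "afn_config")
}

#' Tiny architecture for fast experiments and tests
#' @param ... overrides passed to [afn_config()].
#' @export
afn_config_tiny <- function(...) {
  afn_config(widths = c(4L, 8L, 16L, 16L, 16L), depths = c(1L, 1L, 1L), ...)
}

#' Loss weights of the adaptive fusion loss
#'
#' Defaults are the recommended coefficients alpha = sqrt(2)/2 for BCE
#' and beta = gamma = 1 + sqrt(2)/2 for Dice and boundary terms: BCE is
#' moderately down-weighted while region overlap and boundary accuracy
#' get larger weights.
#'
#' @param alpha,beta,gamma non-negative weights of BCE, Dice and
#'   boundary components.
#' @param xi smoothing constant of the Dice loss denominator.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = sqrt(2) / 2, beta = 1 + sqrt(2) / 2,
                         gamma = 1 + sqrt(2) / 2, xi = 1e-6) {
  if (any(c(alpha, beta, gamma) < 0))
    stop("loss weights alpha, beta, gamma must be non-negative")
  if (xi <= 0) stop("Dice smoothing term `xi` must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, xi = xi),
            class = "loss_weights")
}

#' Training configuration
#'
#' Shipped defaults follow the reference protocol for the Bowl 2018
#' setting: AdamW at initial learning rate 1e-3 annealed by a cosine
#' schedule to 1e-5, beta1 = 0.9, batch size 8, 200 epochs, 256x256
#' inputs with random rotation/flip/scale augmentation.
#'
#' @param lr,min_lr initial and final learning rate of the cosine
#'   schedule.
#' @param optimizer `"adamw"` or `"adam"` (Adam = AdamW with zero decay).
#' @param beta1,beta2,eps Adam moment coefficients.
#' @param weight_decay decoupled weight decay (AdamW).
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param input_size spatial size images are resized to.
#' @param warmup_epochs linear learning-rate warmup epochs before the
#'   cosine schedule starts (0 disables; useful when compressing the
#'   schedule to few epochs).
#' @param clip_norm global gradient-norm clip (Inf disables).
#' @param restarts number of random initialisations raced for one epoch
#'   before the best (by validation Dice) continues training.  Narrow
#'   models are init-lottery sensitive; 3 restarts make small-width
#'   runs robust.  1 disables.
#' @param augment enable random rotation/flip/scale augmentation.
#' @param rotation max absolute rotation in degrees.
#' @param scale_range isotropic scale range.
#' @param weights a [loss_weights()] object.
#' @param gradient_scheme finite-difference scheme of the boundary loss
#'   (`"forward"`, `"central"`, `"sobel"`).
#' @param boundary_on compute the boundary-loss gradient field on
#'   `"prob"` (sigmoid of logits, default) or raw `"logit"` scores.
#' @param normalize_distance divide the distance map by the image
#'   diagonal (default off; pixel units).
#' @param threshold probability threshold for binarising predictions.
#' @param split_frac training fraction of the train/validation split.
#' @param seed seed controlling split, shuffling, augmentation and
#'   initialisation.
#' @param deterministic keep every random draw tied to `seed`.
#' @param out_dir where checkpoints, history and logs are written.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, min_lr = 1e-5, optimizer = "adamw",
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 1e-2, batch_size = 8L,
                         epochs = 200L, input_size = 256L,
                         warmup_epochs = 0L, clip_norm = Inf,
                         restarts = 1L, augment = TRUE,
                         rotation = 90, scale_range = c(0.8, 1.25),
                         weights = loss_weights(),
                         gradient_scheme = "forward",
                         boundary_on = "prob",
                         normalize_distance = FALSE, threshold = 0.5,
                         split_frac = 0.8, seed = 42L,
                         deterministic = TRUE, out_dir = NULL) {
  if (lr <= 0 || min_lr <= 0) stop("learning rates must be > 0")
  if (min_lr > lr) stop("`min_lr` must not exceed `lr`")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  if (split_frac <= 0 || split_frac >= 1)
    stop("`split_frac` must lie strictly between 0 and 1")
  optimizer <- match.arg(optimizer, c("adamw", "adam"))
  gradient_scheme <- match.arg(gradient_scheme,
                               c("forward", "central", "sobel"))
  boundary_on <- match.arg(boundary_on, c("prob", "logit"))
  structure(
    list(lr = lr, min_lr = min_lr, optimizer = optimizer, beta1 = beta1,
         beta2 = beta2, eps = eps, weight_decay = weight_decay,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         input_size = as.integer(input_size),
         warmup_epochs = as.integer(warmup_epochs), clip_norm = clip_norm,
         restarts = max(1L, as.integer(restarts)),
         augment = isTRUE(augment),
         rotation = rotation, scale_range = scale_range, weights = weights,
         gradient_scheme = gradient_scheme, boundary_on = boundary_on,
         normalize_distance = isTRUE(normalize_distance),
         threshold = threshold, split_frac = split_frac,
         seed = as.integer(seed), deterministic = isTRUE(deterministic),
         out_dir = out_dir),
    class = "train_config")
}

#' Named configuration presets
#'
#' `bowl2018`: 256x256 inputs, batch 8, 200 epochs, AdamW + cosine
#' annealing.  `monuseg`: 224x224 inputs, batch 4, 300 epochs, Adam.
#'
#' @param name preset name.
#' @param ... overrides forwarded to [train_config()].
#' @export
train_preset <- function(name = c("bowl2018", "monuseg"), ...) {
  name <- match.arg(name)
  if (name == "bowl2018")
    train_config(input_size = 256L, batch_size = 8L, epochs = 200L,
                 optimizer = "adamw", ...)
  else
    train_config(input_size = 224L, batch_size = 4L, epochs = 300L,
                 optimizer = "adam", weight_decay = 0, ...)
}

#' Read an experiment configuration from a YAML file
#'
#' The document has `model`, `loss`, `train` and `data` sections; keys
#' map 1:1 onto [afn_config()], [loss_weights()] and [train_config()]
#' arguments (e.g. `loss.alpha`, `train.lr`, `model.widths`).
#'
#' @param path YAML file.
#' @return list with elements `model` (`afn_config`), `train`
#'   (`train_config`) and `data` (a plain list of paths).
#' @export
config_read <- function(path) {
  doc <- yaml::read_yaml(path)
  model <- do.call(afn_config, as_config_args(doc$model, afn_config))
  largs <- as_config_args(doc$loss, loss_weights)
  weights <- do.call(loss_weights, largs)
  targs <- as_config_args(doc$train, train_config)
  loss_extra <- doc$loss[intersect(
    names(doc$loss), c("gradient_scheme", "boundary_on",
                       "normalize_distance"))]
  train <- do.call(train_config,
                   c(targs, list(weights = weights), loss_extra))
  list(model = model, train = train, data = doc$data)
}

as_config_args <- function(x, fn) {
  if (is.null(x)) return(list())
  x[intersect(names(x), names(formals(fn)))]
}

#' Write an experiment configuration to a YAML file
#' @param model an `afn_config`.
#' @param train a `train_config`.
#' @param data optional list of data paths.
#' @param path output YAML file.
#' @export
config_write <- function(model, train, data = NULL, path) {
  w <- train$weights
  doc <- list(
    model = unclass(model),
    loss = list(alpha = w$alpha, beta = w$beta, gamma = w$gamma, xi = w$xi,
                gradient_scheme = train$gradient_scheme,
                boundary_on = train$boundary_on,
                normalize_distance = train$normalize_distance),
    train = unclass(train)[setdiff(names(train),
                                   c("weights", "gradient_scheme",
                                     "boundary_on", "normalize_distance"))],
    data = data)
  yaml::write_yaml(doc, path)
  invisible(path)
}

# evaluate `code` under `seed`, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}
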