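# Training: AdamW with cosine learning-rate annealing, seeded
# train/validation split, per-epoch history and checkpointing;
# evaluation and prediction helpers.

#' Cosine annealing learning-rate schedule
#'
#' Closed form `min_lr + (lr - min_lr) * (1 + cos(pi (e-1)/(E-1))) / 2`
#' for epoch `e` of `E`: starts at `lr`, ends exactly at `min_lr`.
#'
#' @param epoch 1-based epoch.
#' @param epochs total epochs.
#' @param lr,min_lr initial and final learning rates.
#' @export
cosine_lr <- function(epoch, epochs, lr, min_lr) {
  if (epochs <= 1L) return(lr)
  min_lr + 0.5 * (lr - min_lr) * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

adamw_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st
}

# scale all gradients so their global L2 norm is at most `clip`
clip_gradients <- function(params, clip) {
  if (!is.finite(clip)) return(invisible(NULL))
  sq <- 0
  for (p in params) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
  gn <- sqrt(sq)
  if (gn > clip)
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * (clip / gn)
  invisible(NULL)
}

# cosine schedule preceded by an optional linear warmup
schedule_lr <- function(epoch, config) {
  wu <- config$warmup_epochs
  if (wu > 0L && epoch <= wu) return(config$lr * epoch / (wu + 1L))
  cosine_lr(epoch - wu, config$epochs - wu, config$lr, config$min_lr)
}

adamw_step <- function(params, st, lr, beta1, beta2, eps, weight_decay) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    upd <- (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
    p$value <- p$value - lr * (upd + weight_decay * p$value)
  }
  invisible(NULL)
}

# deterministic hash of (seed, id) onto [0, 1); multiplicative hashing
# by irrational constants equidistributes even near-identical ids
split_score <- function(id, seed) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 1000000007
  (h * 0.6180339887498949 + (seed %% 2147483647) * 0.7071067811865476) %% 1
}

#' Seeded train/validation split
#'
#' Membership of each sample depends only on `(seed, id)`: ids whose
#' hash score falls below `split_frac` train, the rest validate.  The
#' two sets are disjoint and cover the dataset; if either comes out
#' empty the extreme-scored sample is moved across.
#'
#' @param ids character ids.
#' @param seed integer seed.
#' @param split_frac training fraction.
#' @return list with `train` and `val` index vectors.
#' @export
split_dataset <- function(ids, seed, split_frac = 0.8) {
  sc <- vapply(ids, split_score, numeric(1L), seed = seed)
  tr <- which(sc < split_frac)
  va <- which(sc >= split_frac)
  if (length(va) == 0L && length(tr) > 1L) {
    mv <- tr[which.max(sc[tr])]
    va <- mv
    tr <- setdiff(tr, mv)
  }
  if (length(tr) == 0L && length(va) > 1L) {
    mv <- va[which.min(sc[va])]
    tr <- mv
    va <- setdiff(va, mv)
  }
  list(train = tr, val = va)
}

load_batch <- function(data, idx) {
  samples <- lapply(idx, function(i) dataset_get(data, i))
  list(images = lapply(samples, `[[`, "image"),
       masks = lapply(samples, `[[`, "mask"),
       ids = vapply(samples, `[[`, character(1L), "id"))
}

#' Train an AFN-Net
#'
#' Splits the data by seeded id hashing, optimises the adaptive fusion
#' loss with AdamW (or Adam) under cosine learning-rate annealing, logs
#' per-epoch training loss components and validation metrics, and saves
#' the best-validation-Dice checkpoint (ties resolved to the earlier
#' epoch) plus a final checkpoint.  Fully deterministic for a fixed
#' config and seed.
#'
#' @param config a [train_config()].
#' @param data a `dataset_handle`.
#' @param model_config an [afn_config()]; defaults to the tiny
#'   architecture.
#' @param val_data optional explicit validation handle; when given,
#'   `data` is used for training in full (no split).
#' @return list with `model`, `history` (data.frame), `best_checkpoint`,
#'   `final_checkpoint`, `norm_stats` and the split indices.
#' @export
train <- function(config, data, model_config = afn_config_tiny(),
                  val_data = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (length(data) == 0L) stop("training data handle is empty")
  out_dir <- config$out_dir %||% tempfile("afn_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "train.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)

  if (is.null(val_data)) {
    sp <- split_dataset(data$ids, config$seed, config$split_frac)
    tr_idx <- sp$train; va_idx <- sp$val
    va_data <- data
  } else {
    tr_idx <- seq_len(length(data))
    va_idx <- seq_len(length(val_data))
    va_data <- val_data
  }
  tr_batch0 <- load_batch(data, tr_idx)
  norm_stats <- compute_norm_stats(tr_batch0$images)

  wd <- if (config$optimizer == "adamw") config$weight_decay else 0
  w <- config$weights

  # one optimisation pass over the training set followed by validation;
  # returns the history row for `epoch`
  run_epoch <- function(st, epoch) {
    lr <- schedule_lr(epoch, config)
    order_idx <- tr_idx[sample.int(length(tr_idx))]
    comp_sum <- c(total = 0, bce = 0, dice = 0, boundary = 0)
    nb <- 0L
    for (b0 in seq(1L, length(order_idx), by = config$batch_size)) {
      idx <- order_idx[b0:min(b0 + config$batch_size - 1L,
                              length(order_idx))]
      bt <- load_batch(data, idx)
      ab <- augment_batch(bt$images, bt$masks, config, training = TRUE)
      x <- normalize_batch(ab$images, norm_stats)
      ag_zero_grad(st$params)
      loss <- with_grad({
        logits <- afn_forward(st$model, x, training = TRUE)
        ag_aflm(logits, ab$masks, w, config$gradient_scheme,
                config$boundary_on, config$normalize_distance)
      })
      comp <- loss$components
      if (!is.finite(comp$total))
        stop(sprintf(
          "non-finite loss (%g) at epoch %d for batch ids: %s",
          comp$total, epoch, paste(bt$ids, collapse = ", ")))
      ag_backward(loss)
      clip_gradients(st$params, config$clip_norm)
      adamw_step(st$params, st$opt, lr, config$beta1, config$beta2,
                 config$eps, wd)
      comp_sum <- comp_sum + unlist(comp[c("total", "bce", "dice",
                                           "boundary")])
      nb <- nb + 1L
    }
    comp_mean <- comp_sum / nb
    val <- evaluate(st$model, va_data, config, indices = va_idx,
                    norm_stats = norm_stats)
    data.frame(
      epoch = epoch, lr = lr, loss = comp_mean[["total"]],
      bce = comp_mean[["bce"]], dice_loss = comp_mean[["dice"]],
      boundary = comp_mean[["boundary"]],
      val_iou = val$summary[["iou"]], val_dice = val$summary[["dice"]])
  }

  new_state <- function(mseed) {
    cfg_r <- model_config
    cfg_r$seed <- as.integer(mseed)
    model <- build_afn_net(cfg_r)
    params <- collect_params(model$blocks)
    list(model = model, params = params, opt = adamw_init(params))
  }

  # race `restarts` initialisations for one epoch, keep the best by
  # validation Dice (narrow models are init-lottery sensitive)
  history <- list()
  if (config$restarts > 1L) {
    cand_best <- NULL
    for (r in seq_len(config$restarts)) {
      st_r <- new_state(model_config$seed + (r - 1L) * 1000L)
      set.seed(config$seed + r - 1L)
      row <- run_epoch(st_r, 1L)
      logf("restart %d (init seed %d): epoch-1 val_dice %.4f", r,
           model_config$seed + (r - 1L) * 1000L, row$val_dice)
      if (is.null(cand_best) || row$val_dice > cand_best$row$val_dice)
        cand_best <- list(st = st_r, row = row)
    }
    st <- cand_best$st
    history[[1L]] <- cand_best$row
    first_epoch <- 2L
    set.seed(config$seed + 131071L)
  } else {
    st <- new_state(model_config$seed)
    first_epoch <- 1L
    set.seed(config$seed)
  }

  best <- list(dice = -Inf, epoch = NA_integer_)
  best_path <- file.path(out_dir, "best.rds")
  final_path <- file.path(out_dir, "final.rds")
  ck_extra <- function(epoch) list(norm_stats = norm_stats,
                                   train_config = config, epoch = epoch)
  if (length(history) > 0L && history[[1L]]$val_dice > best$dice) {
    best <- list(dice = history[[1L]]$val_dice, epoch = 1L)
    save_checkpoint(st$model, best_path, extra = ck_extra(1L))
  }

  for (epoch in seq(first_epoch, length.out = config$epochs - first_epoch + 1L)) {
    row <- run_epoch(st, epoch)
    history[[epoch]] <- row
    logf("epoch %d lr %.3e loss %.4f val_dice %.4f", epoch, row$lr,
         row$loss, row$val_dice)
    if (row$val_dice > best$dice) {
      best <- list(dice = row$val_dice, epoch = epoch)
      save_checkpoint(st$model, best_path, extra = ck_extra(epoch))
    }
  }
  model <- st$model
  save_checkpoint(model, final_path, extra = ck_extra(config$epochs))
  history <- do.call(rbind, history)
  utils::write.csv(history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  list(model = model, history = history, best_checkpoint = best_path,
       final_checkpoint = final_path, best_epoch = best$epoch,
       norm_stats = norm_stats, train_idx = tr_idx, val_idx = va_idx,
       out_dir = out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a model or checkpoint on a dataset
#'
#' Runs inference (resize + normalise only), thresholds the
#' probabilities and computes per-image metrics and their aggregate.
#'
#' @param model an `afn_net` or the path to a checkpoint file.
#' @param data a `dataset_handle`.
#' @param config a [train_config()] (threshold, input size).
#' @param indices subset of samples to evaluate (default all).
#' @param norm_stats normalisation statistics; taken from the
#'   checkpoint when loading one.
#' @param aggregate per-image mean (default) or pixel-pooled scores.
#' @param csv,json optional output paths for the report.
#' @return a `metrics_report`.
#' @export
evaluate <- function(model, data, config, indices = NULL,
                     norm_stats = NULL, aggregate = "per_image",
                     csv = NULL, json = NULL) {
  if (is.character(model)) {
    ck <- load_checkpoint(model)
    model <- ck$model
    norm_stats <- norm_stats %||% ck$extra$norm_stats
  }
  if (is.null(norm_stats))
    stop("`norm_stats` are required when evaluating a bare model")
  if (is.null(indices)) indices <- seq_len(length(data))
  bt <- load_batch(data, indices)
  ab <- augment_batch(bt$images, bt$masks, config, training = FALSE)
  n <- length(indices)
  S <- config$input_size
  pred <- array(0, c(n, 1L, S, S))
  bs <- max(1L, config$batch_size)
  for (b0 in seq(1L, n, by = bs)) {
    sel <- b0:min(b0 + bs - 1L, n)
    x <- normalize_batch(ab$images[sel, , , , drop = FALSE], norm_stats)
    pred[sel, , , ] <- afn_predict(model, x)
  }
  bin <- (pred >= config$threshold) * 1
  rep <- evaluate_masks(bin, ab$masks, aggregate = aggregate, ids = bt$ids)
  write_metrics(rep, csv = csv, json = json)
  rep
}

#' Write per-image probability and binary-mask PNGs
#'
#' @param model an `afn_net` or checkpoint path.
#' @param data a `dataset_handle`.
#' @param config a [train_config()].
#' @param out_dir destination directory (`<id>_prob.png`,
#'   `<id>_mask.png`).
#' @param norm_stats normalisation statistics (from the checkpoint when
#'   omitted and `model` is a path).
#' @export
predict_to_dir <- function(model, data, config, out_dir,
                           norm_stats = NULL) {
  if (is.character(model)) {
    ck <- load_checkpoint(model)
    model <- ck$model
    norm_stats <- norm_stats %||% ck$extra$norm_stats
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(length(data))) {
    s <- dataset_get(data, i)
    ab <- augment_batch(list(s$image), list(s$mask), config,
                        training = FALSE)
    x <- normalize_batch(ab$images, norm_stats)
    prob <- afn_predict(model, x)[1L, 1L, , ]
    png::writePNG(prob, file.path(out_dir, paste0(s$id, "_prob.png")))
    png::writePNG((prob >= config$threshold) * 1,
                  file.path(out_dir, paste0(s$id, "_mask.png")))
  }
  invisible(out_dir)
}

#' Loss-weight ablation runs
#'
#' Trains and evaluates the model once per (alpha, beta, gamma) triple
#' and returns one row per triple with the aggregate metrics — the
#' shape of a weight-coefficient ablation table.
#'
#' @param triples list of numeric length-3 vectors.
#' @param config a [train_config()].
#' @param data a `dataset_handle`.
#' @param model_config an [afn_config()].
#' @param csv optional output CSV path.
#' @return data.frame with columns ratio, iou, dice, precision, recall,
#'   specificity.
#' @export
ablate_weights <- function(triples, config, data,
                           model_config = afn_config_tiny(), csv = NULL) {
  rows <- lapply(triples, function(tw) {
    cfg <- config
    cfg$weights <- loss_weights(tw[1L], tw[2L], tw[3L],
                                xi = config$weights$xi)
    cfg$out_dir <- tempfile("afn_ablate_")
    fit <- train(cfg, data, model_config)
    rep <- evaluate(fit$model, data, cfg, indices = fit$val_idx,
                    norm_stats = fit$norm_stats)
    data.frame(ratio = paste(signif(tw, 4), collapse = ":"),
               iou = rep$summary[["iou"]], dice = rep$summary[["dice"]],
               precision = rep$summary[["precision"]],
               recall = rep$summary[["recall"]],
               specificity = rep$summary[["specificity"]])
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

#' Single-batch overfit check
#'
#' Repeatedly optimises the adaptive fusion loss on one fixed batch — a
#' fast sanity check that the full architecture, loss and optimiser can
#' drive the training Dice towards 1.  Uses a deliberately aggressive
#' learning rate suited to memorising a handful of images rather than
#' the full training protocol.
#'
#' @param images,masks lists of paired (3, H, W) / (1, H, W) arrays.
#' @param model_config an [afn_config()].
#' @param steps maximum optimisation steps.
#' @param lr constant learning rate.
#' @param weights a [loss_weights()].
#' @param eval_every evaluate the training Dice every this many steps.
#' @param stop_dice stop early once the training Dice reaches this.
#' @return list with `dice` (final training Dice), `steps_run`, `model`
#'   and the per-evaluation `trace` data.frame.
#' @export
fit_single_batch <- function(images, masks, model_config = afn_config_tiny(),
                             steps = 300L, lr = 5e-3,
                             weights = loss_weights(), eval_every = 10L,
                             stop_dice = Inf) {
  n <- length(images)
  d <- dim(images[[1L]])
  x <- array(0, c(n, d[1L], d[2L], d[3L]))
  G <- array(0, c(n, 1L, d[2L], d[3L]))
  for (i in seq_len(n)) {
    x[i, , , ] <- images[[i]]
    G[i, , , ] <- masks[[i]]
  }
  x <- normalize_batch(x, compute_norm_stats(images))
  model <- build_afn_net(model_config)
  params <- collect_params(model$blocks)
  opt <- adamw_init(params)
  dist <- distance_map(extract_boundary(G))
  trace <- list()
  dice <- 0
  step <- 0L
  while (step < steps) {
    step <- step + 1L
    ag_zero_grad(params)
    loss <- with_grad({
      logits <- afn_forward(model, x, training = TRUE)
      ag_aflm(logits, G, weights, dist = dist)
    })
    ag_backward(loss)
    adamw_step(params, opt, lr, 0.9, 0.999, 1e-8, 1e-2)
    if (step %% eval_every == 0L || step == steps) {
      pred <- (afn_predict(model, x) >= 0.5) * 1
      dice <- evaluate_masks(pred, G)$summary[["dice"]]
      trace[[length(trace) + 1L]] <-
        data.frame(step = step, loss = loss$components$total, dice = dice)
      if (dice >= stop_dice) break
    }
  }
  list(dice = dice, steps_run = step, model = model,
       trace = do.call(rbind, trace))
}
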