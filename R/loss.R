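# Adaptive fusion loss: binary cross-entropy + Dice + a
# distance-transform boundary loss, with configurable weights.
#
# All public loss functions are plain numeric functions of a logit batch
# P and a binary mask batch G, both (batch, 1, H, W).  `ag_aflm()` is
# the differentiable counterpart used by the trainer.

as_mask_batch <- function(x, what = "mask") {
  if (is.matrix(x)) x <- array(x, c(1L, 1L, nrow(x), ncol(x)))
  check_fmap(x, what)
  x
}

check_binary <- function(G, what = "mask") {
  if (!all(G == 0 | G == 1))
    stop(sprintf("%s must be binary (values exactly 0 or 1)", what))
  invisible(G)
}

check_same_shape <- function(P, G) {
  if (!identical(dim(P), dim(G)))
    stop(sprintf("shape mismatch: logits (%s) vs masks (%s)",
                 paste(dim(P), collapse = "x"),
                 paste(dim(G), collapse = "x")))
  invisible(NULL)
}

# inner boundary of one binary matrix: foreground pixels with at least
# one differing 4-neighbour inside the image
boundary_mat <- function(m) {
  H <- nrow(m); W <- ncol(m)
  d <- matrix(FALSE, H, W)
  if (H > 1L) {
    dv <- m[-H, , drop = FALSE] != m[-1L, , drop = FALSE]
    d[-H, ] <- d[-H, ] | dv
    d[-1L, ] <- d[-1L, ] | dv
  }
  if (W > 1L) {
    dh <- m[, -W, drop = FALSE] != m[, -1L, drop = FALSE]
    d[, -W] <- d[, -W] | dh
    d[, -1L] <- d[, -1L] | dh
  }
  (m != 0) & d
}

#' Extract the discrete boundary of binary masks
#'
#' Uses the inner-boundary convention: a pixel belongs to the boundary
#' iff it is foreground and at least one of its 4-neighbours (within the
#' image) carries a different label.  Positions outside the image
#' contribute no label change, so an all-foreground mask has an empty
#' boundary.
#'
#' @param G binary mask batch (batch, 1, H, W), or a single H x W
#'   matrix.
#' @return a 0/1 array of the same shape marking boundary pixels.
#' @export
extract_boundary <- function(G) {
  was_mat <- is.matrix(G)
  G <- as_mask_batch(G)
  check_binary(G)
  out <- array(0, dim(G))
  for (n in seq_len(dim(G)[1L]))
    out[n, 1L, , ] <- boundary_mat(matrix(G[n, 1L, , ], dim(G)[3L]))
  if (was_mat) matrix(out[1L, 1L, , ], dim(G)[3L]) else out
}

#' Euclidean distance map to a boundary set
#'
#' For every pixel, the exact Euclidean distance (in pixel units) to the
#' nearest boundary pixel, computed with a two-pass exact distance
#' transform.  An empty boundary yields an all-zero map by convention
#' (the infimum over the empty set is left undefined; zero keeps the
#' boundary loss finite on empty tiles).
#'
#' @param boundary 0/1 boundary array from [extract_boundary()] (batch
#'   array or single matrix).
#' @return real-valued array of the same shape, zero exactly on
#'   boundary pixels when the boundary is non-empty.
#' @export
distance_map <- function(boundary) {
  if (is.matrix(boundary))
    return(cpp_edt(boundary))
  check_fmap(boundary, "boundary map")
  out <- array(0, dim(boundary))
  for (n in seq_len(dim(boundary)[1L]))
    out[n, 1L, , ] <- cpp_edt(matrix(boundary[n, 1L, , ], dim(boundary)[3L]))
  out
}

# finite-difference taps (drow, dcol, weight) per scheme; shifts are
# clamped at the image border (replicate padding)
grad_taps <- function(scheme) {
  switch(scheme,
    forward = list(
      gx = list(c(0, 1, 1), c(0, 0, -1)),
      gy = list(c(1, 0, 1), c(0, 0, -1))),
    central = list(
      gx = list(c(0, 1, 0.5), c(0, -1, -0.5)),
      gy = list(c(1, 0, 0.5), c(-1, 0, -0.5))),
    sobel = list(
      gx = list(c(-1, 1, 1), c(0, 1, 2), c(1, 1, 1),
                c(-1, -1, -1), c(0, -1, -2), c(1, -1, -1)),
      gy = list(c(1, -1, 1), c(1, 0, 2), c(1, 1, 1),
                c(-1, -1, -1), c(-1, 0, -2), c(-1, 1, -1))),
    stop(sprintf("unknown gradient scheme '%s'", scheme)))
}

shift_clamp <- function(p, dr, dc) {
  H <- nrow(p); W <- ncol(p)
  p[pmin(pmax(seq_len(H) + dr, 1L), H),
    pmin(pmax(seq_len(W) + dc, 1L), W), drop = FALSE]
}

# adjoint of shift_clamp: scatter-add with clamped indices
shift_clamp_adj <- function(u, dr, dc) {
  H <- nrow(u); W <- ncol(u)
  ridx <- pmin(pmax(seq_len(H) + dr, 1L), H)
  cidx <- pmin(pmax(seq_len(W) + dc, 1L), W)
  a <- rowsum(u, ridx)
  b <- rowsum(t(a), cidx)
  gp <- matrix(0, H, W)
  gp[as.integer(rownames(a)), as.integer(rownames(b))] <- t(b)
  gp
}

apply_taps <- function(p, taps) {
  out <- matrix(0, nrow(p), ncol(p))
  for (t in taps) out <- out + t[3L] * shift_clamp(p, t[1L], t[2L])
  out
}

apply_taps_adj <- function(u, taps) {
  out <- matrix(0, nrow(u), ncol(u))
  for (t in taps) out <- out + t[3L] * shift_clamp_adj(u, t[1L], t[2L])
  out
}

grad_components <- function(p, scheme) {
  tp <- grad_taps(scheme)
  list(gx = apply_taps(p, tp$gx), gy = apply_taps(p, tp$gy))
}

#' Gradient magnitude of a prediction map
#'
#' Per pixel, `sqrt(gx^2 + gy^2)` of the finite-difference gradient.
#' The default scheme is forward differences with replicate padding (the
#' last row/column difference is zero); `"central"` and `"sobel"` are
#' alternatives.
#'
#' @param prob single-channel map: an H x W matrix or a (batch, 1, H, W)
#'   array, typically the sigmoid-transformed prediction.
#' @param scheme finite-difference scheme.
#' @return array of the same shape.
#' @export
gradient_magnitude <- function(prob, scheme = c("forward", "central",
                                                "sobel")) {
  scheme <- match.arg(scheme)
  gm1 <- function(m) {
    g <- grad_components(m, scheme)
    sqrt(g$gx^2 + g$gy^2)
  }
  if (is.matrix(prob)) return(gm1(prob))
  check_fmap(prob, "prediction map")
  out <- array(0, dim(prob))
  for (n in seq_len(dim(prob)[1L]))
    out[n, 1L, , ] <- gm1(matrix(prob[n, 1L, , ], dim(prob)[3L]))
  out
}

#' Binary cross-entropy loss on logits
#'
#' `-(1/|Omega|) sum[G log sigma(P) + (1-G) log(1 - sigma(P))]`,
#' averaged over all pixels and the batch, evaluated in the numerically
#' stable log-sum-exp form so large logits of either sign stay finite.
#'
#' @param P logit batch (batch, 1, H, W).
#' @param G binary mask batch of the same shape.
#' @return scalar loss.
#' @export
bce_loss <- function(P, G) {
  P <- as_mask_batch(P, "logits"); G <- as_mask_batch(G)
  check_same_shape(P, G)
  check_binary(G)
  mean(pmax(P, 0) - P * G + log1p(exp(-abs(P))))
}

#' Smoothed Dice loss on logits
#'
#' `1 - (2 sum sigma(P) G + xi) / (sum sigma(P) + sum G + xi)` with the
#' sums over all pixels of each image and the result averaged over the
#' batch.  The smoothing term `xi` keeps the empty/empty case at 0.
#'
#' @inheritParams bce_loss
#' @param xi positive smoothing constant.
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(P, G, xi = 1e-6) {
  if (xi <= 0) stop("Dice smoothing term `xi` must be > 0")
  P <- as_mask_batch(P, "logits"); G <- as_mask_batch(G)
  check_same_shape(P, G)
  check_binary(G)
  n <- dim(P)[1L]
  per <- vapply(seq_len(n), function(i) {
    s <- sigmoid(P[i, 1L, , ])
    g <- G[i, 1L, , ]
    1 - (2 * sum(s * g) + xi) / (sum(s) + sum(g) + xi)
  }, numeric(1L))
  mean(per)
}

#' Distance-transform boundary loss
#'
#' Discretises the boundary integral as the per-image mean over pixels
#' of `||grad sigma(P)||_2 * D_G`, where `D_G` is the Euclidean distance
#' map to the ground-truth boundary, averaged over the batch.  Constant
#' predictions and empty ground-truth boundaries both give exactly 0.
#'
#' @inheritParams bce_loss
#' @param scheme finite-difference scheme for the gradient field.
#' @param on compute the gradient field on `"prob"` (sigmoid of P,
#'   default) or on the raw `"logit"` scores.
#' @param normalize divide the distance map by the image diagonal.
#' @return scalar loss, always >= 0.
#' @export
boundary_loss <- function(P, G, scheme = "forward", on = "prob",
                          normalize = FALSE) {
  P <- as_mask_batch(P, "logits"); G <- as_mask_batch(G)
  check_same_shape(P, G)
  check_binary(G)
  scheme <- match.arg(scheme, c("forward", "central", "sobel"))
  on <- match.arg(on, c("prob", "logit"))
  d <- dim(P)
  scale <- if (normalize) 1 / sqrt(d[3L]^2 + d[4L]^2) else 1
  per <- vapply(seq_len(d[1L]), function(i) {
    g <- matrix(G[i, 1L, , ], d[3L])
    D <- cpp_edt(boundary_mat(g)) * scale
    p <- matrix(P[i, 1L, , ], d[3L])
    field <- if (on == "prob") sigmoid(p) else p
    gc <- grad_components(field, scheme)
    mean(sqrt(gc$gx^2 + gc$gy^2) * D)
  }, numeric(1L))
  mean(per)
}

#' Adaptive fusion loss: weighted BCE + Dice + boundary
#'
#' `L = alpha * BCE + beta * Dice + gamma * Boundary`.  Default weights
#' are `alpha = sqrt(2)/2`, `beta = gamma = 1 + sqrt(2)/2` (see
#' [loss_weights()]).
#'
#' @inheritParams bce_loss
#' @param w a [loss_weights()] object.
#' @param scheme,on,normalize boundary-loss options, see
#'   [boundary_loss()].
#' @return list with elements `total`, `bce`, `dice`, `boundary` (the
#'   three components unweighted).
#' @export
aflm_total <- function(P, G, w = loss_weights(), scheme = "forward",
                       on = "prob", normalize = FALSE) {
  stopifnot(inherits(w, "loss_weights"))
  bce <- bce_loss(P, G)
  dice <- dice_loss(P, G, w$xi)
  bnd <- boundary_loss(P, G, scheme, on, normalize)
  list(total = w$alpha * bce + w$beta * dice + w$gamma * bnd,
       bce = bce, dice = dice, boundary = bnd)
}

# Differentiable total loss.  `p` may be a tensor node (training) or a
# plain array; the distance map depends only on G and is treated as a
# constant.  Returns a scalar node (or plain scalar) whose $components
# attribute carries the unweighted parts.
ag_aflm <- function(p, G, w = loss_weights(), scheme = "forward",
                    on = "prob", normalize = FALSE, dist = NULL) {
  pv <- ag_value(p)
  check_same_shape(pv, G)
  d <- dim(pv)
  n <- d[1L]; npx <- d[3L] * d[4L]
  scale <- if (normalize) 1 / sqrt(d[3L]^2 + d[4L]^2) else 1
  if (is.null(dist)) dist <- distance_map(extract_boundary(G)) * scale
  s <- sigmoid(pv)
  # bce
  bce <- mean(pmax(pv, 0) - pv * G + log1p(exp(-abs(pv))))
  # dice (cache per-image sums)
  num <- den <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i, 1L, , ]; gi <- G[i, 1L, , ]
    num[i] <- 2 * sum(si * gi) + w$xi
    den[i] <- sum(si) + sum(gi) + w$xi
  }
  dice <- mean(1 - num / den)
  # boundary (cache gradient fields)
  taps <- grad_taps(scheme)
  gxs <- gys <- gms <- vector("list", n)
  bnd_per <- numeric(n)
  for (i in seq_len(n)) {
    field <- matrix(if (on == "prob") s[i, 1L, , ] else pv[i, 1L, , ], d[3L])
    gxs[[i]] <- apply_taps(field, taps$gx)
    gys[[i]] <- apply_taps(field, taps$gy)
    gms[[i]] <- sqrt(gxs[[i]]^2 + gys[[i]]^2)
    bnd_per[i] <- mean(gms[[i]] * matrix(dist[i, 1L, , ], d[3L]))
  }
  bnd <- mean(bnd_per)
  total <- w$alpha * bce + w$beta * dice + w$gamma * bnd
  out <- ag_op(total, list(p), function(g) {
    gp <- array(0, d)
    # bce term
    gp <- gp + w$alpha * (s - G) / length(pv)
    # dice term
    for (i in seq_len(n)) {
      si <- s[i, 1L, , ]; gi <- G[i, 1L, , ]
      dl_ds <- -(2 * gi * den[i] - num[i]) / den[i]^2
      gp[i, 1L, , ] <- gp[i, 1L, , ] +
        (w$beta / n) * dl_ds * si * (1 - si)
    }
    # boundary term
    for (i in seq_len(n)) {
      Dm <- matrix(dist[i, 1L, , ], d[3L])
      gm <- gms[[i]]
      sel <- gm > 0
      ux <- uy <- matrix(0, d[3L], d[4L])
      ux[sel] <- Dm[sel] * gxs[[i]][sel] / gm[sel]
      uy[sel] <- Dm[sel] * gys[[i]][sel] / gm[sel]
      dfield <- apply_taps_adj(ux, taps$gx) + apply_taps_adj(uy, taps$gy)
      dfield <- dfield / npx
      if (on == "prob") {
        si <- matrix(s[i, 1L, , ], d[3L])
        dfield <- dfield * si * (1 - si)
      }
      gp[i, 1L, , ] <- gp[i, 1L, , ] + (w$gamma / n) * dfield
    }
    list(g * gp)
  })
  attr2 <- list(bce = bce, dice = dice, boundary = bnd, total = total)
  if (is_ag(out)) out$components <- attr2 else attr(out, "components") <- attr2
  out
}
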