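# Paired geometric augmentation (rotation, flips, isotropic scale) with
# resize and normalisation.  Image planes are sampled bilinearly, masks
# with nearest neighbour so they stay binary; border coordinates are
# clamped (replicate padding).

# forward map: centred input coords -> centred output coords,
# t = s * R(theta) * F(u), then rescaled to the output raster
aug_params <- function(config) {
  list(angle = runif(1, -config$rotation, config$rotation),
       scale = runif(1, config$scale_range[1L], config$scale_range[2L]),
       flip_h = runif(1) < 0.5,
       flip_v = runif(1) < 0.5)
}

identity_params <- function() {
  list(angle = 0, scale = 1, flip_h = FALSE, flip_v = FALSE)
}

#' Map input pixel coordinates through recorded augmentation parameters
#'
#' Applies the same forward transform the resampler inverts: flip, then
#' rotation and isotropic scaling about the image centre, then the
#' resize onto the output raster.  Useful for verifying that mask
#' geometry (e.g. centroids) moves consistently with the image.
#'
#' @param coords matrix with columns (row, col), 0-based input pixel
#'   coordinates.
#' @param params transform parameters recorded by [augment_batch()].
#' @param in_size,out_size input and output (H, W).
#' @return matrix of output coordinates.
#' @export
augment_map_coords <- function(coords, params, in_size, out_size) {
  if (length(in_size) == 1L) in_size <- c(in_size, in_size)
  if (length(out_size) == 1L) out_size <- c(out_size, out_size)
  th <- params$angle * pi / 180
  u_r <- coords[, 1L] - (in_size[1L] - 1) / 2
  u_c <- coords[, 2L] - (in_size[2L] - 1) / 2
  if (params$flip_v) u_r <- -u_r
  if (params$flip_h) u_c <- -u_c
  t_r <- params$scale * (u_r * cos(th) - u_c * sin(th))
  t_c <- params$scale * (u_r * sin(th) + u_c * cos(th))
  cbind(t_r * out_size[1L] / in_size[1L] + (out_size[1L] - 1) / 2,
        t_c * out_size[2L] / in_size[2L] + (out_size[2L] - 1) / 2)
}

# inverse map: 0-based output pixel grid -> 0-based input coords
inverse_coords <- function(params, in_size, out_size) {
  th <- params$angle * pi / 180
  o_r <- rep(seq_len(out_size[1L]) - 1, times = out_size[2L]) -
    (out_size[1L] - 1) / 2
  o_c <- rep(seq_len(out_size[2L]) - 1, each = out_size[1L]) -
    (out_size[2L] - 1) / 2
  t_r <- o_r * in_size[1L] / out_size[1L]
  t_c <- o_c * in_size[2L] / out_size[2L]
  u_r <- (t_r * cos(th) + t_c * sin(th)) / params$scale
  u_c <- (-t_r * sin(th) + t_c * cos(th)) / params$scale
  if (params$flip_v) u_r <- -u_r
  if (params$flip_h) u_c <- -u_c
  list(r = u_r + (in_size[1L] - 1) / 2, c = u_c + (in_size[2L] - 1) / 2)
}

warp_plane <- function(m, src, out_size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  if (method == "nearest") {
    ri <- pmin(pmax(round(src$r) + 1, 1), H)
    ci <- pmin(pmax(round(src$c) + 1, 1), W)
    return(matrix(m[cbind(ri, ci)], out_size[1L], out_size[2L]))
  }
  r0 <- pmin(pmax(floor(src$r), 0), H - 1)
  c0 <- pmin(pmax(floor(src$c), 0), W - 1)
  fr <- pmin(pmax(src$r - r0, 0), 1)
  fc <- pmin(pmax(src$c - c0, 0), 1)
  r1 <- pmin(r0 + 1, H - 1)
  c1 <- pmin(c0 + 1, W - 1)
  v <- (1 - fr) * (1 - fc) * m[cbind(r0 + 1, c0 + 1)] +
    (1 - fr) * fc * m[cbind(r0 + 1, c1 + 1)] +
    fr * (1 - fc) * m[cbind(r1 + 1, c0 + 1)] +
    fr * fc * m[cbind(r1 + 1, c1 + 1)]
  matrix(v, out_size[1L], out_size[2L])
}

warp_sample <- function(image, mask, params, out_size) {
  in_size <- dim(image)[2:3]
  src <- inverse_coords(params, in_size, out_size)
  img <- array(0, c(dim(image)[1L], out_size))
  for (ch in seq_len(dim(image)[1L]))
    img[ch, , ] <- warp_plane(matrix(image[ch, , ], in_size[1L]), src,
                              out_size, "bilinear")
  mk <- warp_plane(matrix(mask[1L, , ], in_size[1L]), src, out_size,
                   "nearest")
  list(image = img, mask = array(mk, c(1L, out_size)))
}

#' Augment and batch paired images and masks
#'
#' In training mode each pair receives one sampled geometric transform
#' (rotation, horizontal/vertical flip, isotropic scale) applied
#' identically to image and mask, then both are resized to
#' `config$input_size`.  Masks are resampled with nearest neighbour and
#' stay exactly binary.  In evaluation mode only the resize is applied.
#' Intensity normalisation is separate ([normalize_batch()]).
#'
#' @param images list of (3, H, W) arrays.
#' @param masks list of (1, H, W) binary arrays.
#' @param config a [train_config()].
#' @param training sample random transforms (uses the current RNG
#'   stream).
#' @return list with batch arrays `images` (N, 3, S, S), `masks`
#'   (N, 1, S, S) and the recorded per-sample `params`.
#' @export
augment_batch <- function(images, masks, config, training = TRUE) {
  n <- length(images)
  S <- c(config$input_size, config$input_size)
  out_i <- array(0, c(n, 3L, S))
  out_m <- array(0, c(n, 1L, S))
  params <- vector("list", n)
  for (i in seq_len(n)) {
    p <- if (training && config$augment) aug_params(config) else
      identity_params()
    w <- warp_sample(images[[i]], masks[[i]], p, S)
    out_i[i, , , ] <- w$image
    out_m[i, , , ] <- w$mask
    params[[i]] <- p
  }
  list(images = out_i, masks = out_m, params = params)
}

#' Per-channel normalisation statistics of a set of images
#'
#' @param images list of (3, H, W) arrays on \[0, 1\].
#' @return list with `mean` and `sd` (length-3 vectors).
#' @export
compute_norm_stats <- function(images) {
  ch_vals <- lapply(1:3, function(ch)
    unlist(lapply(images, function(im) as.numeric(im[ch, , ]))))
  list(mean = vapply(ch_vals, mean, numeric(1L)),
       sd = vapply(ch_vals, function(v) max(stats::sd(v), 1e-6),
                   numeric(1L)))
}

#' Standardise an image batch with dataset statistics
#'
#' @param x batch array (N, C, H, W) on \[0, 1\].
#' @param stats list from [compute_norm_stats()].
#' @return normalised batch.
#' @export
normalize_batch <- function(x, stats) {
  for (ch in seq_len(dim(x)[2L]))
    x[, ch, , ] <- (x[, ch, , ] - stats$mean[ch]) / stats$sd[ch]
  x
}
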