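# Deterministic synthetic nucleus-image generator.
#
# Emulates fluorescence-microscopy nucleus tiles: 0-N rotated elliptical
# blobs of varying size, eccentricity and intensity on a textured
# background with additive Gaussian noise, together with exact binary
# masks (one file per nucleus on disk, Bowl-2018 stage-1 layout).

#' Specification of the synthetic nucleus generator
#'
#' @param size image height and width in pixels.
#' @param n_range inclusive range of nuclei per image.
#' @param radius range of the ellipse semi-major axis in pixels.
#' @param eccentricity range of the axis ratio a/b (1 = circle).
#' @param overlap may nuclei overlap each other.
#' @param fg_intensity,bg_intensity intensity ranges of nuclei and
#'   background (on \[0, 1\]).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param texture amplitude of the smooth background texture field.
#' @param seed integer seed; together with the sample index it fully
#'   determines each sample (counter-based, order-independent).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = c(64L, 64L), n_range = c(1L, 8L),
                           radius = c(2, 10), eccentricity = c(1, 2.5),
                           overlap = TRUE, fg_intensity = c(0.55, 0.95),
                           bg_intensity = c(0.05, 0.25), noise_sd = 0.05,
                           texture = 0.08, seed = 0L) {
  if (length(size) == 1L) size <- c(size, size)
  n_range <- as.integer(n_range)
  if (n_range[1L] < 0L || n_range[1L] > n_range[2L])
    stop("`n_range` must satisfy 0 <= n_min <= n_max")
  if (radius[1L] < 1) stop("`radius` must be >= 1 pixel")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(size = as.integer(size), n_range = n_range,
                 radius = radius, eccentricity = eccentricity,
                 overlap = isTRUE(overlap), fg_intensity = fg_intensity,
                 bg_intensity = bg_intensity, noise_sd = noise_sd,
                 texture = texture, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic per-sample seed from (seed, index); kept within 32 bits
sample_seed <- function(seed, index) {
  m <- 2147483647
  as.integer((((seed %% m) * 69069 + (index %% m) * 1234567) %% m))
}

# pixel-centre ellipse rasterisation on an H x W grid (0-based coords)
rasterize_ellipse <- function(H, W, cr, cc, a, b, theta) {
  r <- matrix(seq_len(H) - 1, H, W) - cr
  cc_ <- matrix(seq_len(W) - 1, H, W, byrow = TRUE) - cc
  u <- r * cos(theta) + cc_ * sin(theta)
  v <- -r * sin(theta) + cc_ * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic sample
#'
#' Draws the nucleus count uniformly on `n_range`, places rotated
#' ellipses (pixel-centre inclusion rule), composes the image as
#' textured background + per-nucleus intensity + Gaussian noise clipped
#' to \[0, 1\], and returns exact masks.  The random stream is derived
#' from `(spec$seed, index)` only, so any sample can be regenerated
#' independently.
#'
#' @param spec a [synthetic_spec()].
#' @param index sample index (>= 1).
#' @return a `synthetic_sample`: list with `image` (3, H, W) in
#'   \[0, 1\], `mask` (1, H, W) binary, `nuclei` (per-nucleus metadata),
#'   `nucleus_masks` (list of H x W binary matrices whose union equals
#'   `mask`) and `id`.
#' @export
generate_sample <- function(spec, index) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$size[1L]; W <- spec$size[2L]
  with_seed(sample_seed(spec$seed, index), {
    n <- if (spec$n_range[1L] == spec$n_range[2L]) spec$n_range[1L] else
      sample(spec$n_range[1L]:spec$n_range[2L], 1L)
    mask <- matrix(FALSE, H, W)
    nuclei <- list()
    nucleus_masks <- list()
    placed <- 0L
    for (k in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        a <- runif(1, spec$radius[1L], spec$radius[2L])
        b <- a / runif(1, spec$eccentricity[1L], spec$eccentricity[2L])
        theta <- runif(1, 0, pi)
        cr <- runif(1, 0, H - 1)
        cc <- runif(1, 0, W - 1)
        m <- rasterize_ellipse(H, W, cr, cc, a, b, theta)
        if (!any(m)) next
        if (!spec$overlap && any(m & mask)) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(
          paste0("could not place nucleus %d of %d without overlap after ",
                 "200 tries (size %dx%d, radius [%g, %g])"),
          k, n, H, W, spec$radius[1L], spec$radius[2L]))
      placed <- placed + 1L
      mask <- mask | m
      intensity <- runif(1, spec$fg_intensity[1L], spec$fg_intensity[2L])
      nuclei[[placed]] <- list(center = c(cr, cc), axes = c(a, b),
                               rotation = theta, intensity = intensity)
      nucleus_masks[[placed]] <- m
    }
    # smooth low-frequency texture field
    bg <- runif(1, spec$bg_intensity[1L], spec$bg_intensity[2L])
    tex <- matrix(0, H, W)
    for (j in 1:3) {
      fr <- runif(1, 0.5, 2); fc <- runif(1, 0.5, 2)
      ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
      tex <- tex + sin(2 * pi * fr * (seq_len(H) - 1) / H + ph1) %o%
        sin(2 * pi * fc * (seq_len(W) - 1) / W + ph2)
    }
    gray <- bg + spec$texture * tex / 3
    for (k in seq_along(nucleus_masks))
      gray[nucleus_masks[[k]]] <- nuclei[[k]]$intensity
    img <- array(0, c(3L, H, W))
    for (ch in 1:3)
      img[ch, , ] <- pmin(pmax(gray + rnorm(H * W, 0, spec$noise_sd), 0), 1)
    structure(list(
      image = img,
      mask = array(as.numeric(mask), c(1L, H, W)),
      nuclei = nuclei,
      nucleus_masks = lapply(nucleus_masks, function(m) m * 1),
      id = sprintf("synth_%s_%05d", spec$seed, index)),
      class = "synthetic_sample")
  })
}

#' Write a synthetic dataset in Bowl-2018 stage-1 layout
#'
#' Each sample becomes `<id>/images/<id>.png` (8-bit RGB) and
#' `<id>/masks/<k>.png` (one 0/255 PNG per nucleus), plus a
#' `manifest.json` listing ids, seeds and per-sample nucleus counts.
#'
#' @param spec a [synthetic_spec()].
#' @param n_samples number of samples to write.
#' @param out_dir destination directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(spec, n_samples, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite)
    stop(sprintf("output directory '%s' is not empty; use overwrite = TRUE",
                 out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    s <- generate_sample(spec, i)
    sdir <- file.path(out_dir, s$id)
    dir.create(file.path(sdir, "images"), showWarnings = FALSE,
               recursive = TRUE)
    dir.create(file.path(sdir, "masks"), showWarnings = FALSE,
               recursive = TRUE)
    png::writePNG(aperm(s$image, c(2L, 3L, 1L)),
                  file.path(sdir, "images", paste0(s$id, ".png")))
    for (k in seq_along(s$nucleus_masks))
      png::writePNG(s$nucleus_masks[[k]],
                    file.path(sdir, "masks", sprintf("%03d.png", k)))
    entries[[i]] <- list(id = s$id, index = i,
                         seed = sample_seed(spec$seed, i),
                         n_nuclei = length(s$nuclei))
  }
  manifest <- list(spec = unclass(spec), n_samples = n_samples,
                   samples = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
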