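# Dataset handles and readers for Bowl-2018 style mask directories and
# generic paired image/mask directories.

#' Construct a dataset handle from in-memory items
#'
#' @param ids character vector of sample ids.
#' @param getter function(i) returning `list(image, mask)` with image
#'   (3, H, W) in \[0, 1\] and mask (1, H, W) binary.
#' @return a `dataset_handle`.
#' @export
dataset_handle <- function(ids, getter) {
  structure(list(ids = ids, getter = getter, n = length(ids)),
            class = "dataset_handle")
}

#' Number of samples in a dataset handle
#' @param x a `dataset_handle`.
#' @param ... unused.
#' @export
length.dataset_handle <- function(x) x$n

#' Fetch one sample from a dataset handle
#' @param data a `dataset_handle`.
#' @param i sample index.
#' @return list with `image` (3, H, W), `mask` (1, H, W), `id`.
#' @export
dataset_get <- function(data, i) {
  s <- data$getter(i)
  s$id <- data$ids[i]
  s
}

read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) {
    out <- array(0, c(3L, nrow(a), ncol(a)))
    for (ch in 1:3) out[ch, , ] <- a
    return(out)
  }
  a <- a[, , seq_len(min(dim(a)[3L], 3L)), drop = FALSE]
  if (dim(a)[3L] == 1L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
  aperm(a, c(3L, 1L, 2L))
}

read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    ch <- min(dim(a)[3L], 3L)
    if (ch > 1L) {
      for (k in 2:ch)
        if (any(a[, , k] != a[, , 1L]))
          stop(sprintf("mask file '%s' is not monochrome", path))
    }
    a <- a[, , 1L]
  }
  (a != 0) * 1
}

#' Load a Data Science Bowl 2018 stage-1 style dataset
#'
#' Expects one directory per sample containing `images/<id>.png` and
#' `masks/*.png` (one PNG per nucleus).  All mask files of a sample are
#' unioned into a single binary mask (any nonzero pixel becomes
#' foreground).  Samples are ordered lexicographically by id.
#'
#' @param root dataset root directory.
#' @param lazy read PNGs on access (default) instead of eagerly.
#' @return a `dataset_handle`.
#' @export
load_bowl2018 <- function(root, lazy = TRUE) {
  if (!dir.exists(root)) stop(sprintf("dataset root '%s' does not exist", root))
  dirs <- list.dirs(root, recursive = FALSE)
  if (length(dirs) == 0L)
    stop(sprintf("no sample directories found under '%s'", root))
  dirs <- sort(dirs)
  ids <- basename(dirs)
  read_one <- function(i) {
    d <- dirs[i]
    idir <- file.path(d, "images")
    mdir <- file.path(d, "masks")
    if (!dir.exists(idir))
      stop(sprintf("sample '%s' is missing its images/ directory", ids[i]))
    if (!dir.exists(mdir))
      stop(sprintf("sample '%s' is missing its masks/ directory", ids[i]))
    ipng <- sort(dir(idir, pattern = "\\.png$", full.names = TRUE))
    if (length(ipng) == 0L)
      stop(sprintf("sample '%s' has no image PNG", ids[i]))
    img <- read_image_png(ipng[1L])
    mpng <- sort(dir(mdir, pattern = "\\.png$", full.names = TRUE))
    H <- dim(img)[2L]; W <- dim(img)[3L]
    mk <- matrix(0, H, W)
    for (p in mpng) mk <- pmax(mk, read_mask_png(p))
    list(image = img, mask = array(mk, c(1L, H, W)))
  }
  if (lazy) return(dataset_handle(ids, read_one))
  cache <- lapply(seq_along(ids), read_one)
  dataset_handle(ids, function(i) cache[[i]])
}

#' Load a generic paired image/mask directory
#'
#' `images_dir` and `masks_dir` must contain PNGs matched by filename.
#'
#' @param images_dir,masks_dir directories of paired PNGs.
#' @return a `dataset_handle`.
#' @export
load_paired_dir <- function(images_dir, masks_dir) {
  imgs <- sort(dir(images_dir, pattern = "\\.png$"))
  if (length(imgs) == 0L)
    stop(sprintf("no PNG images found under '%s'", images_dir))
  missing <- imgs[!file.exists(file.path(masks_dir, imgs))]
  if (length(missing) > 0L)
    stop(sprintf("masks missing for: %s", paste(missing, collapse = ", ")))
  ids <- sub("\\.png$", "", imgs)
  dataset_handle(ids, function(i) {
    img <- read_image_png(file.path(images_dir, imgs[i]))
    mk <- read_mask_png(file.path(masks_dir, imgs[i]))
    list(image = img, mask = array(mk, c(1L, dim(img)[2L], dim(img)[3L])))
  })
}

#' Build a dataset handle from synthetic samples held in memory
#'
#' @param spec a [synthetic_spec()].
#' @param n number of samples.
#' @return a `dataset_handle` generating samples on access (counter
#'   based, so access order does not matter).
#' @export
synthetic_dataset <- function(spec, n) {
  ids <- vapply(seq_len(n), function(i) sprintf("synth_%s_%05d", spec$seed, i),
                character(1L))
  dataset_handle(ids, function(i) {
    s <- generate_sample(spec, i)
    list(image = s$image, mask = s$mask)
  })
}
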