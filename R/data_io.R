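# Dataset IO: manifest reading, image/mask loading with resizing and
# normalization, and seeded batch index generation. File decoding and
# resampling are delegated to EBImage (PNG/JPEG/TIFF).

#' Read a dataset manifest
#'
#' Expects `<dir>/manifest.csv` with columns `id`, `image_path`, `mask_path`
#' (relative to `dir`) and `split` in `{train, val, test}`. Every referenced
#' file must exist and ids must be unique.
#'
#' @param dir Dataset directory (layout of [write_phantom_dataset()]).
#' @return A tibble with absolute paths.
#' @export
read_manifest <- function(dir) {
  csv <- file.path(dir, "manifest.csv")
  if (!file.exists(csv)) stop("no manifest found at ", csv, call. = FALSE)
  m <- tibble::as_tibble(utils::read.csv(csv, stringsAsFactors = FALSE))
  stopifnot(all(c("id", "image_path", "mask_path", "split") %in% names(m)))
  if (anyDuplicated(m$id)) stop("duplicate ids in manifest", call. = FALSE)
  m$image_path <- file.path(dir, m$image_path)
  m$mask_path <- file.path(dir, m$mask_path)
  for (p in c(m$image_path, m$mask_path)) {
    if (!file.exists(p)) stop("manifest references missing file: ", p, call. = FALSE)
  }
  m
}

# EBImage uses (x, y[, c]) axis order; convert to the package's (C, H, W).
ebimage_to_chw <- function(img) {
  a <- as.array(img)
  if (length(dim(a)) == 2L) {
    array(t(a), c(1L, dim(a)[2], dim(a)[1]))
  } else {
    aperm(a, c(3, 2, 1))
  }
}

#' Load one image/mask pair
#'
#' The image is resized bilinearly to `size x size` and scaled to `[0, 1]`;
#' the mask is resized with nearest-neighbour interpolation (preserving
#' binarity) and binarized at 127/255. Grayscale images get a singleton
#' channel axis.
#'
#' @param image_path,mask_path PNG/JPEG/TIFF files; `mask_path` may be `NA`
#'   for unlabelled images.
#' @param size Target square side (default 256).
#' @return `list(image, mask, id)` with `image` `(C, size, size)` and `mask`
#'   binary `(size, size)` (or `NULL` without a mask).
#' @export
load_sample <- function(image_path, mask_path = NA, size = 256L) {
  if (!file.exists(image_path)) {
    stop("image file not found: ", image_path, call. = FALSE)
  }
  img <- EBImage::readImage(image_path)
  if (any(dim(img)[1:2] != size)) {
    img <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
  }
  image <- ebimage_to_chw(img)
  image <- pmin(pmax(image, 0), 1)
  mask <- NULL
  if (!is.na(mask_path)) {
    if (!file.exists(mask_path)) {
      stop("mask file not found: ", mask_path, call. = FALSE)
    }
    mk <- EBImage::readImage(mask_path)
    if (any(dim(mk)[1:2] != size)) {
      mk <- EBImage::resize(mk, w = size, h = size, filter = "none")
    }
    mka <- as.array(mk)
    if (length(dim(mka)) > 2L) mka <- mka[, , 1] # flatten accidental RGB masks
    mask <- matrix(as.integer(t(mka) > 127 / 255), size, size)
  }
  list(image = image, mask = mask,
       id = tools::file_path_sans_ext(basename(image_path)))
}

#' Load a manifest split into batch-ready arrays
#'
#' @param manifest A tibble from [read_manifest()] (or
#'   [write_phantom_dataset()]).
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @param size Target square side.
#' @return `list(x, y, ids)`: `x` is `(n, C, size, size)`, `y` is
#'   `(n, 1, size, size)`.
#' @export
load_split <- function(manifest, split, size = 256L) {
  rows <- manifest[manifest$split == split, ]
  if (nrow(rows) == 0L) stop("split '", split, "' is empty", call. = FALSE)
  samples <- purrr::pmap(rows[, c("image_path", "mask_path")], function(image_path, mask_path) {
    load_sample(image_path, mask_path, size)
  })
  samples_to_arrays(samples, ids = rows$id)
}

#' Stack samples into batch-ready arrays
#'
#' @param samples List of samples (`list(image, mask, id)`), e.g. one split
#'   of a phantom set.
#' @param ids Optional id vector (defaults to the samples' own ids).
#' @return `list(x, y, ids)` with `x` `(n, C, H, W)` and `y` `(n, 1, H, W)`.
#' @export
samples_to_arrays <- function(samples, ids = NULL) {
  n <- length(samples)
  dimg <- dim(samples[[1]]$image)
  x <- array(0, c(n, dimg[1], dimg[2], dimg[3]))
  y <- array(0, c(n, 1L, dimg[2], dimg[3]))
  for (i in seq_len(n)) {
    x[i, , , ] <- samples[[i]]$image
    y[i, 1, , ] <- samples[[i]]$mask
  }
  list(x = x, y = y,
       ids = ids %||% vapply(samples, function(s) s$id %||% "", character(1)))
}

#' Seeded batch index plan
#'
#' Training epochs reshuffle deterministically from `shuffle_seed + epoch`;
#' without a seed the order is the input order (validation/test). The final
#' partial batch is kept.
#'
#' @param n Number of samples.
#' @param batch_size Batch size.
#' @param shuffle_seed Integer seed or `NULL` for no shuffling.
#' @param epoch Epoch number (1-based) mixed into the seed.
#' @return List of integer index vectors.
#' @export
make_batches <- function(n, batch_size, shuffle_seed = NULL, epoch = 1L) {
  if (n < 1L) stop("empty split", call. = FALSE)
  ord <- if (is.null(shuffle_seed)) {
    seq_len(n)
  } else {
    withr::with_seed(as.integer(shuffle_seed) + as.integer(epoch) - 1L, sample(n))
  }
  split(ord, ceiling(seq_along(ord) / batch_size))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
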