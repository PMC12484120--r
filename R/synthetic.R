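# Synthetic ultrasound phantoms: speckle-noised, low-contrast images with one
# or more hypoechoic elliptical lesions and exact ground-truth masks. The
# generator emulates the qualitative challenges of clinical B-mode imagery
# (multiplicative speckle, weak lesion/background contrast, smooth echo
# texture); it is not an acoustic simulation.

#' Phantom generator configuration
#'
#' @param n_images Number of image/mask pairs.
#' @param size Square image side in pixels (default 256).
#' @param lesions_per_image Integer range `c(min, max)` of lesions per image.
#' @param lesion_axis_fraction Range of ellipse semi-axes as a fraction of
#'   `size`; the upper bound must stay below 0.5 so a lesion fits inside the
#'   frame.
#' @param contrast_drop Lesion intensity attenuation in (0, 1); 0 renders
#'   lesions invisible in expectation (mask still nonzero). Default 0.45, a
#'   markedly hypoechoic lesion.
#' @param speckle_shape Shape of the mean-1 multiplicative gamma speckle;
#'   smaller is noisier. `Inf` disables speckle. Default 4.
#' @param blur_sigma Gaussian point-spread blur in pixels (default 1).
#' @param seed Integer seed; generation is a pure function of the config.
#' @param rgb If `TRUE`, emit a 3-channel dermoscopy-like tinted variant.
#' @param hyperechoic If `TRUE`, lesions are brighter instead of darker.
#' @param speckle_model `"gamma"` (default) or `"rayleigh"` multiplicative
#'   noise, both scaled to unit mean.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(n_images = 16L, size = 256L,
                           lesions_per_image = c(1L, 3L),
                           lesion_axis_fraction = c(0.05, 0.25),
                           contrast_drop = 0.45, speckle_shape = 4,
                           blur_sigma = 1, seed = 1L, rgb = FALSE,
                           hyperechoic = FALSE,
                           speckle_model = c("gamma", "rayleigh")) {
  speckle_model <- match.arg(speckle_model)
  if (length(lesion_axis_fraction) == 1L) {
    lesion_axis_fraction <- rep(lesion_axis_fraction, 2L)
  }
  if (max(lesion_axis_fraction) >= 0.5) {
    stop("lesion_axis_fraction must stay below 0.5 (lesion must fit the frame)",
         call. = FALSE)
  }
  if (length(lesions_per_image) == 1L) lesions_per_image <- rep(lesions_per_image, 2L)
  if (contrast_drop < 0 || contrast_drop >= 1) {
    stop("contrast_drop must lie in [0, 1)", call. = FALSE)
  }
  if (speckle_shape <= 0) stop("speckle_shape must be positive", call. = FALSE)
  if (blur_sigma < 0) stop("blur_sigma must be nonnegative", call. = FALSE)
  structure(
    list(n_images = as.integer(n_images), size = as.integer(size),
         lesions_per_image = as.integer(lesions_per_image),
         lesion_axis_fraction = lesion_axis_fraction,
         contrast_drop = contrast_drop, speckle_shape = speckle_shape,
         blur_sigma = blur_sigma, seed = as.integer(seed), rgb = isTRUE(rgb),
         hyperechoic = isTRUE(hyperechoic), speckle_model = speckle_model),
    class = "phantom_config"
  )
}

# Truncated-and-renormalized Gaussian blur matrix along one axis; rows sum to
# one so edges are not darkened.
gauss_blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    w <- exp(-((j - i)^2) / (2 * sigma^2))
    A[i, j] <- w / sum(w)
  }
  A
}

# Smooth background echo texture: a coarse Gaussian grid upsampled bilinearly.
phantom_background <- function(size) {
  coarse <- matrix(stats::rnorm(64), 8, 8)
  A <- resize_matrix(8, size, "bilinear")
  field <- A %*% coarse %*% t(A)
  0.55 + 0.12 * field
}

rasterize_ellipse <- function(size, cx, cy, a, b, theta) {
  h <- matrix(seq_len(size), size, size)
  w <- matrix(seq_len(size), size, size, byrow = TRUE)
  u <- (h - cx) * cos(theta) + (w - cy) * sin(theta)
  v <- -(h - cx) * sin(theta) + (w - cy) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

generate_one_phantom <- function(cfg, id) {
  size <- cfg$size
  img <- phantom_background(size)
  mask <- matrix(FALSE, size, size)
  k <- if (cfg$lesions_per_image[1] == cfg$lesions_per_image[2]) {
    cfg$lesions_per_image[1]
  } else {
    sample(cfg$lesions_per_image[1]:cfg$lesions_per_image[2], 1L)
  }
  for (i in seq_len(k)) {
    fr <- cfg$lesion_axis_fraction
    a <- stats::runif(1, fr[1], fr[2]) * size
    b <- stats::runif(1, fr[1], fr[2]) * size
    theta <- stats::runif(1, 0, pi)
    margin <- max(a, b) + 2
    cx <- if (2 * margin < size) stats::runif(1, margin, size - margin) else size / 2
    cy <- if (2 * margin < size) stats::runif(1, margin, size - margin) else size / 2
    mask <- mask | rasterize_ellipse(size, cx, cy, a, b, theta)
  }
  fac <- if (cfg$hyperechoic) 1 + cfg$contrast_drop else 1 - cfg$contrast_drop
  img[mask] <- img[mask] * fac
  if (is.finite(cfg$speckle_shape)) {
    noise <- if (cfg$speckle_model == "gamma") {
      stats::rgamma(size * size, shape = cfg$speckle_shape, rate = cfg$speckle_shape)
    } else {
      # Rayleigh scaled to unit mean
      sqrt(-2 * log(stats::runif(size * size))) * sqrt(2 / pi) / sqrt(2)
    }
    img <- img * matrix(noise, size, size)
  }
  if (cfg$blur_sigma > 0) {
    A <- gauss_blur_matrix(size, cfg$blur_sigma)
    img <- A %*% img %*% t(A)
  }
  img <- pmin(pmax(img, 0), 1)
  image <- if (cfg$rgb) {
    grad <- matrix(seq(0, 0.08, length.out = size), size, size, byrow = TRUE)
    arr <- array(0, c(3L, size, size))
    arr[1, , ] <- pmin(img * 0.95 + 0.12 + grad, 1)
    arr[2, , ] <- pmin(img * 0.75 + 0.08 + 0.5 * grad, 1)
    arr[3, , ] <- pmin(img * 0.60 + 0.05, 1)
    arr
  } else {
    array(img, c(1L, size, size))
  }
  list(image = image, mask = matrix(as.integer(mask), size, size), id = id)
}

#' Generate a set of synthetic lesion phantoms
#'
#' Each sample is built by drawing a smooth background echo texture, placing
#' `k` random ellipses (rotation, position and semi-axes within
#' `lesion_axis_fraction * size`), attenuating lesion interiors by
#' `contrast_drop`, multiplying by unit-mean speckle, Gaussian-blurring and
#' clipping to `[0, 1]`. The mask is the rasterized lesion union. The output
#' is bitwise-reproducible for a given config.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_set`: list of samples, each `list(image, mask, id)`
#'   with `image` a `(channels, size, size)` array and `mask` a binary
#'   `(size, size)` matrix.
#' @export
generate_phantoms <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  samples <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_images), function(i) {
      generate_one_phantom(config, sprintf("phantom_%03d", i))
    })
  })
  structure(samples, class = "phantom_set", config = config)
}

#' Split samples into train/validation/test sets
#'
#' Seeded shuffle, then a disjoint exhaustive partition with sizes
#' `round(fractions * n)` (remainder to the last split).
#'
#' @param samples A list (e.g. a `phantom_set`).
#' @param fractions Length-3 nonnegative fractions summing to 1.
#' @param seed Shuffle seed.
#' @return Named list `train`, `val`, `test` of sample lists.
#' @export
split_samples <- function(samples, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L) {
    stop("fractions must be three values summing to 1", call. = FALSE)
  }
  n <- length(samples)
  ord <- withr::with_seed(seed, sample(n))
  k1 <- round(fractions[1] * n)
  k2 <- round(fractions[2] * n)
  k2 <- min(k2, n - k1)
  list(
    train = samples[ord[seq_len(k1)]],
    val = samples[ord[k1 + seq_len(k2)]],
    test = samples[ord[setdiff(seq_len(n), seq_len(k1 + k2))]]
  )
}

#' Write a phantom set to disk in the dataset layout
#'
#' Writes `<dir>/images/<id>.png` and `<dir>/masks/<id>.png` (8-bit; masks in
#' {0, 255}) plus `<dir>/manifest.csv` with columns `id`, `image_path`,
#' `mask_path` (relative) and `split`.
#'
#' @param samples A `phantom_set` or list of samples.
#' @param dir Output directory (created if missing).
#' @param fractions,seed Passed to [split_samples()].
#' @return The manifest tibble (with absolute paths), invisibly.
#' @export
write_phantom_dataset <- function(samples, dir, fractions = c(0.6, 0.2, 0.2),
                                  seed = 1L) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  parts <- split_samples(samples, fractions, seed)
  rows <- list()
  for (sp in names(parts)) {
    for (s in parts[[sp]]) {
      ip <- file.path("images", paste0(s$id, ".png"))
      mp <- file.path("masks", paste0(s$id, ".png"))
      img <- s$image
      out <- if (dim(img)[1] == 1L) img[1, , ] else aperm(img, c(2, 3, 1))
      png::writePNG(out, file.path(dir, ip))
      png::writePNG(s$mask + 0, file.path(dir, mp)) # {0,1} doubles -> {0,255}
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = s$id, image_path = ip, mask_path = mp, split = sp
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest$image_path <- file.path(dir, manifest$image_path)
  manifest$mask_path <- file.path(dir, manifest$mask_path)
  invisible(manifest)
}
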