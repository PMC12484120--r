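# Shared helpers: tiny seeded fixtures and independent brute-force oracles.

rand_fmap <- function(n, c, h, w, seed = NULL) {
  gen <- function() array(stats::rnorm(n * c * h * w), c(n, c, h, w))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

rand_mask <- function(h, w, p = 0.4, seed = NULL) {
  gen <- function() matrix(stats::rbinom(h * w, 1, p), h, w)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Naive O(everything) dilated convolution, the independent oracle.
naive_conv <- function(x, W, b, dil) {
  d <- dim(x); wd <- dim(W); k <- wd[1]
  pad <- (k - 1) * dil / 2
  out <- array(0, c(d[1], wd[4], d[3], d[4]))
  for (n in seq_len(d[1])) for (o in seq_len(wd[4])) {
    for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
      s <- b[o]
      for (cc in seq_len(d[2])) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        ih <- h - pad + (ki - 1) * dil
        iw <- w - pad + (kj - 1) * dil
        if (ih >= 1 && ih <= d[3] && iw >= 1 && iw <= d[4]) {
          s <- s + x[n, cc, ih, iw] * W[ki, kj, cc, o]
        }
      }
      out[n, o, h, w] <- s
    }
  }
  out
}

# Brute-force pixel-loop confusion tally.
naive_counts <- function(pred, y) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && y[i] == 1) tp <- tp + 1
    else if (pred[i] == 0 && y[i] == 0) tn <- tn + 1
    else if (pred[i] == 1 && y[i] == 0) fp <- fp + 1
    else fn <- fn + 1
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Small three-split phantom dataset in memory.
tiny_data <- function(n = 6, size = 16, seed = 1) {
  ph <- generate_phantoms(phantom_config(n_images = n, size = size, seed = seed))
  sp <- split_samples(ph, c(0.5, 0.25, 0.25), seed = seed)
  list(train = samples_to_arrays(sp$train),
       val = samples_to_arrays(sp$val),
       test = samples_to_arrays(sp$test))
}



tiny_model_config <- function(...) {
  model_config(stage_widths = c(4L, 8L, 12L, 16L), reduction = 4L,
               spatial_kernel = 3L, ...)
}
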