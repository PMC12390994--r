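# shared fixtures: everything is generated in code, nothing on disk

small_config <- function(size = 96L, noise_sd = 0, seed = 1L) {
  scenario_config(image_size = size, noise_sd = noise_sd, seed = seed)
}

# independent brute-force confusion oracle: explicit per-pixel loop
loop_confusion <- function(pred, ref) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; r <- ref[i, j]
      if (p == 1L && r == 1L) tp <- tp + 1L
      else if (p == 1L && r == 0L) fp <- fp + 1L
      else if (p == 0L && r == 1L) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# random binary mask with given foreground probability
random_mask <- function(n, prob = 0.3) {
  matrix(as.integer(runif(n * n) < prob), n, n)
}

# constant-colour labeled image fixture
flat_labeled_image <- function(size = 16L, id = "src", fg_frac = 0.25) {
  mask <- matrix(0L, size, size)
  k <- round(fg_frac * size * size)
  if (k > 0) mask[seq_len(k)] <- 1L
  img <- array(0.5, dim = c(size, size, 3))
  labeled_image(img, mask, id)
}
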