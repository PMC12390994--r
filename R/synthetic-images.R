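#' Simulate a synthetic canopy image with a known panicle mask
#'
#' Renders randomly placed elliptical panicle-coloured blobs on a
#' background-coloured canvas until the mask's foreground fraction lies
#' within `tol` of `target_coverage` (exactly 0 or 1 at the extremes).
#' Candidate ellipses that would overshoot `target_coverage + tol` are
#' skipped, so placement terminates close to the target; per-pixel Gaussian
#' colour jitter is added afterwards. Realism is a non-goal: the blobs
#' exist to exercise tiling, colour-rule segmentation and the coverage
#' arithmetic against exact ground truth.
#'
#' @param target_coverage Desired foreground fraction in `[0, 1]`.
#' @param config A [scenario_config()] supplying `image_size`,
#'   `panicle_color` and `background_color`.
#' @param seed Integer seed.
#' @param color_jitter_sd Per-pixel Gaussian colour noise (0 disables).
#' @param tol Acceptance half-width on the achieved coverage.
#' @param max_attempts Placement attempts before failing with an error.
#' @return A list of class `synthetic_image_pair`: `image` (`[H, W, 3]`
#'   array in `[0, 1]`), `mask` (binary `[H, W]` matrix) and
#'   `true_coverage` (exactly `sum(mask) / length(mask)`).
#' @examples
#' pair <- simulate_image_pair(0.25, scenario_config(image_size = 96), seed = 7)
#' pair$true_coverage
#' @export
simulate_image_pair <- function(target_coverage,
                                config = scenario_config(),
                                seed = 1L,
                                color_jitter_sd = 0.03,
                                tol = 0.01,
                                max_attempts = 50000L) {
  if (target_coverage < 0 || target_coverage > 1) {
    abort("`target_coverage` must lie in [0, 1].")
  }
  n <- config$image_size
  npix <- n * n
  withr_seed(seed, {
    mask <- matrix(0L, n, n)
    if (target_coverage >= 1) {
      mask[] <- 1L
    } else if (target_coverage > 0) {
      # ellipse semi-axes scale with the canvas so a single blob covers
      # roughly 0.1-1% of the image and the +-tol stopping rule is reachable
      ax_lo <- max(2, 0.015 * n)
      ax_hi <- max(3, 0.055 * n)
      attempts <- 0L
      n_fg <- 0
      frac <- 0
      while (frac < target_coverage - tol) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          abort(sprintf(
            "failed to reach coverage %.3f within %d ellipse placements (at %.3f); raise `max_attempts` or `tol`.",
            target_coverage, max_attempts, frac
          ))
        }
        cy <- runif(1, 1, n); cx <- runif(1, 1, n)
        ry <- runif(1, ax_lo, ax_hi); rx <- runif(1, ax_lo, ax_hi)
        theta <- runif(1, 0, pi)
        # evaluate the ellipse only inside its bounding box
        r_max <- max(ry, rx)
        ri <- max(1L, floor(cy - r_max)):min(n, ceiling(cy + r_max))
        ci <- max(1L, floor(cx - r_max)):min(n, ceiling(cx + r_max))
        dy <- matrix(ri - cy, length(ri), length(ci))
        dx <- matrix(rep(ci - cx, each = length(ri)), length(ri), length(ci))
        u <- dy * cos(theta) + dx * sin(theta)
        v <- -dy * sin(theta) + dx * cos(theta)
        hit <- (u / ry)^2 + (v / rx)^2 <= 1
        patch <- mask[ri, ci, drop = FALSE]
        added <- sum(hit & patch == 0L)
        if ((n_fg + added) / npix <= target_coverage + tol) {
          patch[hit] <- 1L
          mask[ri, ci] <- patch
          n_fg <- n_fg + added
          frac <- n_fg / npix
        }
      }
    }
    image <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) {
      plane <- ifelse(mask == 1L, config$panicle_color[ch],
                      config$background_color[ch])
      if (color_jitter_sd > 0) plane <- plane + rnorm(npix, 0, color_jitter_sd)
      image[, , ch] <- clamp01(plane)
    }
    structure(
      list(image = image, mask = mask, true_coverage = sum(mask) / npix),
      class = "synthetic_image_pair"
    )
  })
}

#' @export
print.synthetic_image_pair <- function(x, ...) {
  cat(sprintf("synthetic image pair: %d x %d, coverage %.4f\n",
              nrow(x$mask), ncol(x$mask), x$true_coverage))
  invisible(x)
}
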