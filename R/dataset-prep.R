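#' Crop a raster into square tiles
#'
#' Splits an image or mask into `tile` x `tile` pieces in row-major order
#' (left-to-right, then top-to-bottom). Both dimensions must be integer
#' multiples of `tile`; resize first otherwise (see [plot_coverage()],
#' which standardises to 1536 so nine 512-pixel tiles result).
#'
#' @param x `[H, W]` matrix or `[H, W, 3]` array.
#' @param tile Tile side in pixels.
#' @return List of `(H/tile) * (W/tile)` tiles; concatenating them with
#'   [stitch_tiles()] reconstructs the input exactly.
#' @examples
#' length(crop_to_tiles(matrix(0, 1536, 1536))) # 9
#' @export
crop_to_tiles <- function(x, tile = 512L) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  if (h %% tile != 0 || w %% tile != 0) {
    abort(sprintf("dimensions %d x %d are not multiples of tile size %d; resize first.",
                  h, w, tile))
  }
  nr <- h %/% tile; nc <- w %/% tile
  out <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      ri <- ((i - 1L) * tile + 1L):(i * tile)
      cj <- ((j - 1L) * tile + 1L):(j * tile)
      out[[k]] <- if (length(d) == 3L) x[ri, cj, , drop = FALSE] else x[ri, cj, drop = FALSE]
    }
  }
  out
}

#' Reassemble tiles produced by [crop_to_tiles()]
#'
#' @param tiles List of equally sized tiles in row-major order.
#' @param nrow_tiles,ncol_tiles Tile grid shape.
#' @return The stitched raster.
#' @export
stitch_tiles <- function(tiles, nrow_tiles, ncol_tiles) {
  stopifnot(length(tiles) == nrow_tiles * ncol_tiles)
  t1 <- tiles[[1]]
  d <- dim(t1)
  tile_h <- d[1]; tile_w <- d[2]
  full_dim <- if (length(d) == 3L) c(nrow_tiles * tile_h, ncol_tiles * tile_w, d[3]) else
    c(nrow_tiles * tile_h, ncol_tiles * tile_w)
  out <- array(t1[1] * 0, dim = full_dim)
  k <- 0L
  for (i in seq_len(nrow_tiles)) {
    for (j in seq_len(ncol_tiles)) {
      k <- k + 1L
      ri <- ((i - 1L) * tile_h + 1L):(i * tile_h)
      cj <- ((j - 1L) * tile_w + 1L):(j * tile_w)
      if (length(d) == 3L) out[ri, cj, ] <- tiles[[k]] else out[ri, cj] <- tiles[[k]]
    }
  }
  if (length(d) == 2L && all(unlist(tiles) %in% c(0L, 1L))) out <- as_binary_mask(out)
  out
}

#' Construct a labeled image (image + binary panicle mask)
#'
#' @param image `[H, W, 3]` array in `[0, 1]`.
#' @param mask Binary matrix matching `image` in height/width (0 =
#'   background, 1 = panicle).
#' @param source_id Identifier of the originating capture; augmented
#'   copies keep their source's id so splits can group them.
#' @param augmentation_tag One of `"none"`, `"noise"`,
#'   `"brightness_contrast"`, `"rescale"`, or combinations joined by `+`.
#' @return A list of class `labeled_image`.
#' @export
labeled_image <- function(image, mask, source_id, augmentation_tag = "none") {
  check_image(image)
  check_mask(mask)
  if (!all(dim(image)[1:2] == dim(mask))) {
    abort("`image` and `mask` dimensions differ.")
  }
  structure(list(image = image, mask = mask, source_id = source_id,
                 augmentation_tag = augmentation_tag),
            class = "labeled_image")
}

#' Photometric adjustments
#'
#' `adjust_brightness_contrast()` rescales contrast about mid-grey and then
#' multiplies by the brightness factor, clamping to `[0, 1]`; factors of 1
#' are the identity. `add_gaussian_noise()` adds clamped i.i.d. Gaussian
#' noise. Masks are never touched by photometric operations.
#'
#' @param image `[H, W, 3]` array.
#' @param brightness,contrast Multiplicative factors.
#' @param sd Noise standard deviation as a fraction of dynamic range.
#' @return Adjusted image array.
#' @name photometric
NULL

#' @rdname photometric
#' @export
adjust_brightness_contrast <- function(image, brightness = 1, contrast = 1) {
  clamp01(((image - 0.5) * contrast + 0.5) * brightness)
}

#' @rdname photometric
#' @export
add_gaussian_noise <- function(image, sd = 0.02) {
  clamp01(image + array(rnorm(length(image), 0, sd), dim = dim(image)))
}

#' Rescale an image/mask pair
#'
#' The image is resized bilinearly, the mask with nearest-neighbour so it
#' stays binary and geometrically consistent. The output size is
#' `round(factor * dim)`; use [fit_to_size()] to restore a fixed tensor
#' shape afterwards.
#'
#' @param image `[H, W, 3]` array.
#' @param mask Binary matrix.
#' @param factor Scale factor (> 0).
#' @return List with rescaled `image` and `mask`.
#' @export
rescale_pair <- function(image, mask, factor) {
  stopifnot(factor > 0)
  h <- max(1L, round(dim(mask)[1] * factor))
  w <- max(1L, round(dim(mask)[2] * factor))
  list(image = resize_raster(image, h, w, "bilinear"),
       mask = resize_raster(mask, h, w, "nearest"))
}

#' Centre-crop or pad a pair back to a fixed size
#'
#' Oversized rasters are centre-cropped; undersized ones are centre-padded
#' with background (image 0, mask 0).
#'
#' @inheritParams rescale_pair
#' @param height,width Target size.
#' @return List with `image` and `mask` of the requested size.
#' @export
fit_to_size <- function(image, mask, height, width) {
  fit1 <- function(x, is_mask) {
    d <- dim(x)
    out <- if (is_mask) matrix(0L, height, width) else array(0, c(height, width, 3))
    # overlap window between source and target, both centred
    src_r <- centred_window(d[1], height)
    src_c <- centred_window(d[2], width)
    dst_r <- centred_window(height, d[1])
    dst_c <- centred_window(width, d[2])
    if (is_mask) {
      out[dst_r, dst_c] <- x[src_r, src_c]
    } else {
      out[dst_r, dst_c, ] <- x[src_r, src_c, ]
    }
    out
  }
  list(image = fit1(image, FALSE), mask = as_binary_mask(fit1(mask, TRUE)))
}

centred_window <- function(n_src, n_dst) {
  keep <- min(n_src, n_dst)
  start <- (n_src - keep) %/% 2L
  (start + 1L):(start + keep)
}

#' Default augmentation factor ranges
#'
#' Brightness and contrast factors are drawn in `[0.8, 1.2]`; the scale
#' factor is drawn from the upscale range `[1.1, 2.0]` or the downscale
#' range `[0.6, 0.9]` with equal probability; Gaussian noise sd defaults
#' to 0.02 of dynamic range.
#'
#' @return Named list of ranges.
#' @export
augment_ranges <- function() {
  list(brightness = c(0.8, 1.2), contrast = c(0.8, 1.2),
       upscale = c(1.1, 2.0), downscale = c(0.6, 0.9), noise_sd = 0.02)
}

check_aug_ranges <- function(ranges, allow_custom = FALSE) {
  if (allow_custom) return(invisible(ranges))
  ref <- augment_ranges()
  for (nm in c("brightness", "contrast", "upscale", "downscale")) {
    r <- ranges[[nm]]
    if (r[1] < ref[[nm]][1] - 1e-12 || r[2] > ref[[nm]][2] + 1e-12) {
      abort(sprintf(
        "`%s` range [%g, %g] falls outside the supported [%g, %g]; set `allow_custom_ranges = TRUE` to override.",
        nm, r[1], r[2], ref[[nm]][1], ref[[nm]][2]))
    }
  }
  invisible(ranges)
}

#' Augment a labeled image
#'
#' One augmented copy applies, in order: random brightness/contrast
#' adjustment, random up- or downscaling (with the mask tracked by
#' nearest-neighbour resampling), optional Gaussian noise, and finally a
#' centre crop/pad back to the original size so tensor shape is constant.
#'
#' @param item A [labeled_image()].
#' @param ops Subset of `c("brightness_contrast", "rescale",
#'   "gaussian_noise")`.
#' @param ranges Factor ranges, see [augment_ranges()].
#' @param keep_size Restore the original height/width after rescaling.
#' @param allow_custom_ranges Permit ranges outside the supported bounds.
#' @return A new `labeled_image` with the same `source_id` and an
#'   `augmentation_tag` describing the applied operations.
#' @export
augment_image <- function(item,
                          ops = c("brightness_contrast", "rescale"),
                          ranges = augment_ranges(),
                          keep_size = TRUE,
                          allow_custom_ranges = FALSE) {
  stopifnot(inherits(item, "labeled_image"))
  ops <- match.arg(ops, c("brightness_contrast", "rescale", "gaussian_noise"),
                   several.ok = TRUE)
  check_aug_ranges(ranges, allow_custom_ranges)
  img <- item$image
  msk <- item$mask
  tags <- character(0)
  d0 <- dim(item$mask)
  if ("brightness_contrast" %in% ops) {
    b <- runif(1, ranges$brightness[1], ranges$brightness[2])
    cc <- runif(1, ranges$contrast[1], ranges$contrast[2])
    img <- adjust_brightness_contrast(img, b, cc)
    tags <- c(tags, "brightness_contrast")
  }
  if ("rescale" %in% ops) {
    up <- runif(1) < 0.5
    f <- if (up) runif(1, ranges$upscale[1], ranges$upscale[2]) else
      runif(1, ranges$downscale[1], ranges$downscale[2])
    rp <- rescale_pair(img, msk, f)
    img <- rp$image; msk <- rp$mask
    tags <- c(tags, "rescale")
  }
  if ("gaussian_noise" %in% ops) {
    img <- add_gaussian_noise(img, ranges$noise_sd)
    tags <- c(tags, "noise")
  }
  if (keep_size && !all(dim(msk) == d0)) {
    fp <- fit_to_size(img, msk, d0[1], d0[2])
    img <- fp$image; msk <- fp$mask
  }
  labeled_image(img, msk, item$source_id, paste(tags, collapse = "+"))
}

#' Augment a dataset with a fixed per-source multiplicity
#'
#' Returns the originals plus `n_copies` augmented variants of each, so
#' `n_copies = 2` triples the dataset (867 sources become 2,601 items).
#'
#' @param items List of [labeled_image()] objects.
#' @param n_copies Augmented copies per source.
#' @param seed Integer seed; augmentation draws are deterministic in it.
#' @inheritParams augment_image
#' @return List of `length(items) * (1 + n_copies)` labeled images.
#' @export
augment_dataset <- function(items, n_copies = 2L,
                            ops = c("brightness_contrast", "rescale"),
                            ranges = augment_ranges(), seed = 1L,
                            allow_custom_ranges = FALSE) {
  withr_seed(seed, {
    out <- vector("list", length(items) * (1L + n_copies))
    k <- 0L
    for (item in items) {
      k <- k + 1L
      out[[k]] <- item
      for (j in seq_len(n_copies)) {
        k <- k + 1L
        out[[k]] <- augment_image(item, ops = ops, ranges = ranges,
                                  allow_custom_ranges = allow_custom_ranges)
      }
    }
    out
  })
}

#' Split items into train/validation/test partitions
#'
#' Partition sizes follow the largest-remainder apportionment of the number
#' of unique sources by `ratios`; shuffling is seed-deterministic. The
#' split is made at *source* level, so all augmented variants of one
#' source land in the same partition (a leakage guard; set `by_source =
#' FALSE` to split at item level instead).
#'
#' @param item_ids Character vector of item identifiers (non-empty).
#' @param source_ids Source identifier per item; defaults to `item_ids`.
#' @param ratios Three positive fractions summing to 1, named
#'   `train`/`validation`/`test`.
#' @param seed Integer seed.
#' @param by_source Split at source level (default) or item level.
#' @return A tibble of class `split_manifest` with columns `item_id`,
#'   `source_id`, `partition`; the apportioned source-level sizes are in
#'   `attr(, "sizes")` and the ratios in `attr(, "ratios")`.
#' @examples
#' table(split_items(sprintf("img%02d", 1:10))$partition)
#' @export
split_items <- function(item_ids, source_ids = item_ids,
                        ratios = c(train = 0.7, validation = 0.2, test = 0.1),
                        seed = 1L, by_source = TRUE) {
  if (length(item_ids) == 0L) abort("`item_ids` is empty.")
  if (length(ratios) != 3L || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-8) {
    abort("`ratios` must be three positive fractions summing to 1.")
  }
  if (length(source_ids) != length(item_ids)) {
    abort("`source_ids` must match `item_ids` in length.")
  }
  units <- if (by_source) unique(source_ids) else item_ids
  if (length(units) < 3L) abort("fewer distinct units than partitions.")
  sizes <- largest_remainder(length(units), ratios)
  part_names <- c("train", "validation", "test")
  withr_seed(seed, {
    shuffled <- sample(units)
    assignment <- rep(part_names, times = sizes)
    unit_part <- setNames(assignment, shuffled)
    partition <- if (by_source) unname(unit_part[source_ids]) else
      unname(unit_part[item_ids])
    out <- tibble(item_id = item_ids, source_id = source_ids,
                  partition = factor(partition, levels = part_names))
    structure(out, sizes = setNames(sizes, part_names), ratios = ratios,
              class = c("split_manifest", class(out)))
  })
}

# largest-remainder apportionment of n by ratios
largest_remainder <- function(n, ratios) {
  q <- n * ratios
  base <- floor(q)
  leftover <- n - sum(base)
  if (leftover > 0) {
    take <- order(q - base, decreasing = TRUE)[seq_len(leftover)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
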