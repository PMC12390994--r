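#' Panicle coverage of a binary mask
#'
#' Coverage is the foreground fraction `PA / (PA + BA)`: panicle pixels
#' over total pixels. Stored as a fraction in `[0, 1]` throughout the
#' package; multiply by 100 only at report boundaries.
#'
#' @param mask Binary matrix.
#' @return Coverage fraction.
#' @export
coverage_from_mask <- function(mask) {
  check_mask(mask)
  sum(mask) / length(mask)
}

#' Colour-box segmentation rule
#'
#' A per-channel acceptance box: a pixel is classified as panicle when all
#' three RGB channels fall inside `[lower, upper]`. This is the package's
#' baseline segmenter, letting the full pipeline run end-to-end on
#' synthetic imagery with a known panicle colour; real deployments plug in
#' a trained model through the same segmenter contract (any function
#' mapping an RGB tile to a same-sized binary mask).
#'
#' @param lower,upper RGB triples in `[0, 1]`.
#' @return A function of class `segmenter` mapping an `[H, W, 3]` tile to
#'   a binary `[H, W]` mask. A degenerate rule (empty acceptance region)
#'   warns and yields all-zero masks.
#' @examples
#' seg <- color_rule_segmenter(c(0.6, 0.5, 0.2), c(1, 1, 0.6))
#' @export
color_rule_segmenter <- function(lower, upper) {
  stopifnot(length(lower) == 3L, length(upper) == 3L)
  degenerate <- any(lower > upper)
  if (degenerate) warn("degenerate colour rule (lower > upper): all-zero masks.")
  f <- function(tile) {
    check_image(tile, "tile")
    if (degenerate) return(matrix(0L, dim(tile)[1], dim(tile)[2]))
    ok <- tile[, , 1] >= lower[1] & tile[, , 1] <= upper[1] &
      tile[, , 2] >= lower[2] & tile[, , 2] <= upper[2] &
      tile[, , 3] >= lower[3] & tile[, , 3] <= upper[3]
    as_binary_mask(ok)
  }
  structure(f, class = c("segmenter", "function"))
}

#' Colour rule matched to a synthetic scenario
#'
#' Builds a colour box centred on the scenario's panicle colour with
#' half-width `margin`; with the default Gaussian colour jitter (sd 0.03)
#' a margin of 0.15 is a 5-sigma band, so misclassification is
#' negligible on synthetic imagery.
#'
#' @param config A [scenario_config()].
#' @param margin Per-channel half-width of the acceptance box.
#' @return A `segmenter` function.
#' @export
scenario_segmenter <- function(config, margin = 0.15) {
  color_rule_segmenter(pmax(config$panicle_color - margin, 0),
                       pmin(config$panicle_color + margin, 1))
}

#' Whole-plot panicle coverage through the tiled pipeline
#'
#' Standardises the image to `size` x `size` (bilinear), splits it into
#' `(size/tile)^2` tiles (nine 512-pixel tiles at the defaults), applies
#' the segmenter to each tile, computes the coverage fraction per tile,
#' and returns the arithmetic mean of the per-tile coverages. For
#' equal-area tiles this mean is exactly the coverage of the stitched
#' mask.
#'
#' @param image `[H, W, 3]` RGB array.
#' @param segmenter A function mapping an RGB tile to a same-sized binary
#'   mask (see [color_rule_segmenter()]).
#' @param size Standardised image side (pixels).
#' @param tile Tile side (pixels); must divide `size`.
#' @return Coverage fraction in `[0, 1]`.
#' @export
plot_coverage <- function(image, segmenter, size = 1536L, tile = 512L) {
  check_image(image)
  if (size %% tile != 0) abort("`tile` must divide `size`.")
  if (!all(dim(image)[1:2] == c(size, size))) {
    image <- resize_raster(image, size, size, "bilinear")
  }
  tiles <- crop_to_tiles(image, tile)
  cov <- vapply(seq_along(tiles), function(i) {
    m <- segmenter(tiles[[i]])
    if (is.null(dim(m)) || !all(dim(m) == dim(tiles[[i]])[1:2])) {
      abort(sprintf("segmenter output for tile %d has the wrong shape.", i))
    }
    if (!all(m %in% c(0L, 1L))) {
      abort(sprintf("segmenter output for tile %d is not binary.", i))
    }
    coverage_from_mask(m)
  }, numeric(1))
  mean(cov)
}

#' Build per-plot coverage series from dated images
#'
#' Runs [plot_coverage()] on each image, groups by plot, sorts by day and
#' averages duplicate same-day acquisitions (a twice-daily camera yields
#' two images per date). Plots with fewer than 5 distinct days are flagged
#' with a warning since the 5-parameter model cannot be fitted to them.
#'
#' @param manifest Data frame with columns `plot_id`, `day` and either
#'   `image` (a list-column of RGB arrays) or `path` (PNG file paths).
#' @param segmenter Segmenter function.
#' @param ... Passed to [plot_coverage()].
#' @return Tibble with columns `plot_id`, `day`, `coverage` and
#'   `n_images` (acquisitions averaged into the observation).
#' @export
build_series <- function(manifest, segmenter, ...) {
  if (nrow(manifest) == 0L) abort("`manifest` is empty.")
  if (!"image" %in% names(manifest) && !"path" %in% names(manifest)) {
    abort("`manifest` needs an `image` list-column or a `path` column.")
  }
  covs <- vapply(seq_len(nrow(manifest)), function(i) {
    img <- if ("image" %in% names(manifest)) manifest$image[[i]] else
      read_image_png(manifest$path[i])
    plot_coverage(img, segmenter, ...)
  }, numeric(1))
  out <- manifest |>
    dplyr::mutate(coverage = covs) |>
    dplyr::group_by(.data$plot_id, .data$day) |>
    dplyr::summarise(coverage = mean(.data$coverage), n_images = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$plot_id, .data$day)
  short <- out |>
    dplyr::count(.data$plot_id) |>
    dplyr::filter(.data$n < 5L)
  if (nrow(short) > 0) {
    warn(sprintf("plots with < 5 observations (too few for a 5-parameter fit): %s",
                 paste(short$plot_id, collapse = ", ")))
  }
  out
}
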