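test_that("tiling is row-major, count-exact and lossless", {
  m <- matrix(as.numeric(seq_len(48 * 48)), 48, 48)
  tiles <- crop_to_tiles(m, 16)
  expect_length(tiles, 9L)
  expect_identical(tiles[[1]], m[1:16, 1:16])
  expect_identical(tiles[[2]], m[1:16, 17:32]) # row-major ordering
  expect_identical(stitch_tiles(tiles, 3, 3), m)

  expect_identical(crop_to_tiles(m, 48)[[1]], m)

  rect <- matrix(runif(32 * 48), 32, 48)
  t6 <- crop_to_tiles(rect, 16)
  expect_length(t6, 6L)
  expect_equal(sum(unlist(t6)), sum(rect), tolerance = 1e-12)

  expect_error(crop_to_tiles(matrix(0, 30, 48), 16), "not multiples")
})

test_that("identity photometric factors leave the image unchanged", {
  img <- array(runif(12 * 12 * 3, 0.2, 0.8), dim = c(12, 12, 3))
  expect_equal(adjust_brightness_contrast(img, 1, 1), img, tolerance = 1e-12)
  out <- adjust_brightness_contrast(img, 1.2, 0.8)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("rescaling keeps the mask binary and roughly preserves its fraction", {
  pair <- simulate_image_pair(0.3, small_config(64), seed = 5, color_jitter_sd = 0)
  rp <- rescale_pair(pair$image, pair$mask, 0.6)
  expect_equal(dim(rp$mask), round(dim(pair$mask) * 0.6))
  expect_true(all(rp$mask %in% c(0L, 1L)))
  frac0 <- coverage_from_mask(pair$mask)
  frac1 <- coverage_from_mask(rp$mask)
  expect_lt(abs(frac1 - frac0), 0.02)

  up <- rescale_pair(pair$image, pair$mask, 1.5)
  expect_lt(abs(coverage_from_mask(up$mask) - frac0), 0.02)
})

test_that("fit_to_size restores the original tensor shape", {
  pair <- simulate_image_pair(0.3, small_config(64), seed = 5)
  rp <- rescale_pair(pair$image, pair$mask, 0.7)
  back <- fit_to_size(rp$image, rp$mask, 64, 64)
  expect_equal(dim(back$image), c(64, 64, 3))
  expect_equal(dim(back$mask), c(64, 64))
  big <- rescale_pair(pair$image, pair$mask, 1.4)
  back2 <- fit_to_size(big$image, big$mask, 64, 64)
  expect_equal(dim(back2$mask), c(64, 64))
})

test_that("a multiplicity of 2 triples the dataset and tags copies", {
  items <- lapply(sprintf("src%02d", 1:12), flat_labeled_image, size = 16L)
  aug <- augment_dataset(items, n_copies = 2, seed = 3)
  expect_length(aug, 36L)
  tags <- vapply(aug, function(x) x$augmentation_tag, character(1))
  expect_equal(sum(tags == "none"), 12L)
  expect_true(all(tags[tags != "none"] == "brightness_contrast+rescale"))
  # copies inherit the source id and keep binary masks and constant shape
  for (it in aug) {
    expect_true(all(it$mask %in% c(0L, 1L)))
    expect_equal(dim(it$mask), c(16L, 16L))
  }
  srcs <- vapply(aug, function(x) x$source_id, character(1))
  expect_equal(sort(unique(srcs)), sprintf("src%02d", 1:12))
  # deterministic per seed
  aug2 <- augment_dataset(items, n_copies = 2, seed = 3)
  expect_identical(aug[[2]]$image, aug2[[2]]$image)
})

test_that("augmentation factor ranges outside the supported bounds are rejected", {
  it <- flat_labeled_image()
  bad <- augment_ranges()
  bad$brightness <- c(0.5, 1.5)
  expect_error(augment_image(it, ranges = bad), "brightness")
  expect_s3_class(augment_image(it, ranges = bad, allow_custom_ranges = TRUE),
                  "labeled_image")
})

test_that("split sizes follow largest-remainder apportionment", {
  sp10 <- split_items(sprintf("im%02d", 1:10), seed = 1)
  expect_equal(unname(table(sp10$partition)[c("train", "validation", "test")]),
               table(factor(c(rep("a", 7), rep("b", 2), "c")))[1:3] |> unname())
  expect_identical(unname(attr(sp10, "sizes")), c(7L, 2L, 1L))

  sp867 <- split_items(sprintf("s%03d", 1:867), seed = 1)
  expect_identical(unname(attr(sp867, "sizes")), c(607L, 173L, 87L))
})

test_that("splits are disjoint, exhaustive, seed-stable and leakage-free", {
  item_ids <- sprintf("item%03d", 1:60)
  source_ids <- rep(sprintf("src%02d", 1:20), each = 3) # 3 augmented variants each
  sp <- split_items(item_ids, source_ids, seed = 5)
  expect_setequal(sp$item_id, item_ids)
  # every source's variants land in exactly one partition
  per_src <- tapply(as.character(sp$partition), sp$source_id,
                    function(x) length(unique(x)))
  expect_true(all(per_src == 1L))
  expect_identical(sp$partition, split_items(item_ids, source_ids, seed = 5)$partition)
  expect_false(identical(sp$partition,
                         split_items(item_ids, source_ids, seed = 6)$partition))
  expect_error(split_items(c("a", "b"), seed = 1), "fewer")
  expect_error(split_items(item_ids, ratios = c(0.5, 0.5, 0.5)), "ratios")
})
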