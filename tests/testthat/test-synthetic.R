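test_that("the canopy generator is deterministic and mask-exact", {
  a <- generate_canopy(canopy_spec(seed = 7), n_lesions = 3)
  b <- generate_canopy(canopy_spec(seed = 7), n_lesions = 3)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(nrow(a$lesions), 3L)
  # requested lesions appear as that many connected components
  regions <- attribute_regions(a$mask)
  expect_identical(nrow(regions), 3L)
  # lesion centres are recorded inside the mask's components
  for (i in seq_len(nrow(a$lesions))) {
    expect_true(a$mask[round(a$lesions$row[i]), round(a$lesions$col[i])])
  }
})

test_that("lesion colour is separated from canopy colour in hue", {
  can <- generate_canopy(canopy_spec(seed = 8), n_lesions = 3)
  img <- can$image
  hue_of <- function(sel) {
    r <- img[, , 1][sel]; g <- img[, , 2][sel]; b <- img[, , 3][sel]
    mean(grDevices::rgb2hsv(r = r, g = g, b = b, maxColorValue = 1)[1, ])
  }
  expect_gt(abs(hue_of(can$mask) - hue_of(!can$mask)), 0.1)
})

test_that("generated images round-trip through PNG without level loss", {
  can <- generate_canopy(canopy_spec(rows = 96, cols = 96, margin = 16,
                                     seed = 9), n_lesions = 1)
  tmp <- withr::local_tempfile(fileext = ".png")
  write_image(can$image, tmp)
  expect_identical(round(read_image(tmp) * 255), round(can$image * 255))
  leaf <- generate_leaf(leaf_spec(seed = 10))
  tmp2 <- withr::local_tempfile(fileext = ".png")
  write_image(leaf$image, tmp2)
  expect_identical(round(read_image(tmp2) * 255), round(leaf$image * 255))
})

test_that("leaf images keep corners clear and masks consistent", {
  for (s in 1:5) {
    leaf <- generate_leaf(leaf_spec(seed = 20 + s))
    # corner 8x8 patches contain no leaf pixels (background-label assumption)
    M <- nrow(leaf$leaf_mask); N <- ncol(leaf$leaf_mask)
    expect_false(any(leaf$leaf_mask[1:8, 1:8]))
    expect_false(any(leaf$leaf_mask[1:8, (N - 7):N]))
    expect_false(any(leaf$leaf_mask[(M - 7):M, 1:8]))
    expect_false(any(leaf$leaf_mask[(M - 7):M, (N - 7):N]))
    # lesions lie on the leaf; leaf fills a plausible fraction of the frame
    expect_true(all(leaf$leaf_mask[leaf$lesion_mask]))
    expect_gt(mean(leaf$leaf_mask), 0.15)
    expect_lt(mean(leaf$leaf_mask), 0.65)
  }
  clean <- generate_leaf(leaf_spec(seed = 30), n_lesions = 0)
  expect_false(any(clean$lesion_mask))
})

test_that("patch training sets land on disk in the class-folder layout", {
  dir <- withr::local_tempdir()
  generate_patch_training_set(5, spec = canopy_spec(rows = 64, cols = 64,
                                                    margin = 8),
                              dir = dir, seed = 42)
  expect_length(list.files(file.path(dir, "healthy")), 5L)
  expect_length(list.files(file.path(dir, "lesion")), 5L)
  ds <- read_patch_dir(dir)
  expect_length(ds$patches, 10L)
  expect_identical(levels(ds$labels), c("healthy", "lesion"))
  expect_identical(dim(ds$patches[[1]]), c(64L, 64L, 3L))
  # in-memory generation with the same seed matches what was written
  mem <- generate_patch_training_set(5, spec = canopy_spec(rows = 64,
                                                           cols = 64,
                                                           margin = 8),
                                     seed = 42)
  expect_identical(round(mem$patches[[1]] * 255), round(ds$patches[[1]] * 255))
})

test_that("the colour-rule oracle is exact on generator output", {
  orc <- oracle_patch_classifier()
  can <- small_canopy(seed = 43, n_lesions = 2)
  spec <- split_spec(96, 144, 32, stride_rows = 32)
  co <- split_image(can$image, spec)
  P <- classify_configuration(co, orc)
  truth <- vapply(seq_len(spec$k1 * spec$k2), function(i) {
    rc <- arrayInd(i, c(spec$k1, spec$k2))
    any(can$mask[(rc[1] - 1) * 32 + 1:32, (rc[2] - 1) * 32 + 1:32])
  }, logical(1))
  expect_identical(as.vector(P >= 0.5), truth)
})
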