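test_that("corner/centre sampling yields the 4 + 6 labeled patches", {
  leaf <- generate_leaf(leaf_spec(seed = 50))
  set.seed(1)
  s <- sample_training_patches(leaf$image)
  expect_length(s$patches, 10L)
  expect_identical(as.vector(table(s$labels)), c(4L, 6L))
  # the four corner anchors
  M <- nrow(leaf$leaf_mask); N <- ncol(leaf$leaf_mask)
  expect_identical(unname(s$positions[1:4, ]),
                   rbind(c(1L, 1L), c(1L, N - 7L), c(M - 7L, 1L),
                         c(M - 7L, N - 7L)))
  # centre patches come from the central third, which is leaf territory
  for (k in 5:10) {
    blk <- leaf$leaf_mask[s$positions[k, 1] + 0:7, s$positions[k, 2] + 0:7]
    expect_true(all(blk))
  }
  set.seed(1)
  s2 <- sample_training_patches(leaf$image)
  expect_identical(s$positions, s2$positions)
  expect_error(sample_training_patches(leaf$image[1:20, 1:20, ]), "too small")
})

test_that("background removal recovers the leaf and zeroes the rest", {
  leaves <- lapply(51:53, function(s) generate_leaf(leaf_spec(seed = s)))
  model <- train_foreground_model(lapply(leaves, `[[`, "image"), seed = 6)
  res <- remove_background(leaves[[1]]$image, model, out_size = NULL)
  truth <- leaves[[1]]$leaf_mask
  iou <- sum(res$mask & truth) / sum(res$mask | truth)
  expect_gte(iou, 0.90)
  # background is exactly (0,0,0) inside the returned crop
  crop_mask <- res$mask[res$bbox[1]:res$bbox[2], res$bbox[3]:res$bbox[4]]
  for (ch in 1:3) {
    plane <- res$image[, , ch]
    expect_true(all(plane[!crop_mask] == 0))
  }
  # resizing lands on the configured dataset shape
  res2 <- remove_background(leaves[[2]]$image, model, out_size = c(264, 400))
  expect_identical(dim(res2$image), c(264L, 400L, 3L))
})

test_that("an all-foreground image crops to itself", {
  leaves <- lapply(54:55, function(s) generate_leaf(leaf_spec(seed = s)))
  model <- train_foreground_model(lapply(leaves, `[[`, "image"), seed = 6)
  # paint a frame entirely with the leaf's interior colour
  leaf <- leaves[[1]]
  inside <- which(leaf$leaf_mask & !leaf$lesion_mask, arr.ind = TRUE)
  px <- inside[which.min(abs(inside[, 1] - 128) + abs(inside[, 2] - 128)), ]
  flat <- array(rep(leaf$image[px[1], px[2], ], each = 96 * 96), c(96, 96, 3))
  res <- remove_background(flat, model, out_size = NULL)
  expect_identical(dim(res$image), dim(flat))
  expect_identical(res$bbox, c(1L, 96L, 1L, 96L))
  # and an all-background image warns and returns uncropped
  bgpx <- which(!leaf$leaf_mask, arr.ind = TRUE)[1, ]
  bg <- array(rep(leaf$image[bgpx[1], bgpx[2], ], each = 96 * 96),
              c(96, 96, 3))
  expect_warning(res0 <- remove_background(bg, model, out_size = NULL),
                 "empty foreground")
  expect_identical(dim(res0$image), dim(bg))
})

test_that("block-classifying the image keeps centre patches in the foreground", {
  leaf <- generate_leaf(leaf_spec(seed = 56))
  model <- train_foreground_model(leaf$image, seed = 6)
  prob <- foreground_probability(leaf$image, model)
  set.seed(2)
  s <- sample_training_patches(leaf$image)
  for (k in 5:10) {
    ctr <- s$positions[k, ] + 3L
    expect_gte(prob[ctr[1], ctr[2]], 0.5)
  }
})
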