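test_that("grid counts match the worked splitting example and edge cases", {
  # 160 x 195 image, 64 px patches, stride 8 -> 13 x 17 grid
  expect_identical(compute_grid(160, 64, 8), 13L)
  expect_identical(compute_grid(195, 64, 8), 17L)
  expect_identical(compute_grid(64, 64, 8), 1L)
  expect_identical(compute_grid(352, 64, 8), 37L)
  expect_identical(compute_grid(576, 64, 8), 65L)
  expect_error(compute_grid(32, 64, 8), "invalid geometry")
  expect_error(compute_grid(64, 64, 0), "invalid geometry")
  expect_error(compute_grid(64, 0, 1), "invalid geometry")
})

test_that("grid counts agree with enumeration of valid start offsets", {
  for (dim in c(1:40, 63, 64, 65, 100, 160, 195)) {
    for (stride in c(1:9, 16)) {
      for (patch in unique(pmin(dim, c(1, 2, 3, 5, 8, 13, 21, 64)))) {
        offsets <- seq(0L, dim - patch, by = stride)
        expect_identical(compute_grid(dim, patch, stride), length(offsets),
                         info = sprintf("dim=%d patch=%d stride=%d",
                                        dim, patch, stride))
      }
    }
  }
})

test_that("splitting extracts the exact source sub-blocks", {
  set.seed(1)
  x <- array(runif(160 * 195 * 3), c(160, 195, 3))
  spec <- split_spec(160, 195, 64, stride_rows = 8)
  co <- split_image(x, spec)
  expect_identical(dim(co$patches), c(13L, 17L))
  expect_length(co$patches, 221L)
  for (k in 1:10) {
    r <- sample(13, 1); c_ <- sample(17, 1)
    expect_identical(co$patches[[r, c_]],
                     x[(r - 1) * 8 + 1:64, (c_ - 1) * 8 + 1:64, , drop = FALSE])
  }
  # exact-fit image is its own single patch
  spec1 <- split_spec(64, 64, 64, stride_rows = 8, stride_cols = 8)
  y <- x[1:64, 1:64, , drop = FALSE]
  co1 <- split_image(y, spec1)
  expect_identical(dim(co1$patches), c(1L, 1L))
  expect_identical(co1$patches[[1, 1]], y)
  expect_error(split_image(x[1:100, , , drop = FALSE], spec), "invalid geometry")
})

test_that("patch-to-pixel mapping places patch pixels at stride offsets", {
  spec <- split_spec(160, 195, 64, stride_rows = 8)
  expect_identical(unname(patch_to_pixel(1, 1, 1, 1, spec)), c(1L, 1L))
  expect_identical(unname(patch_to_pixel(2, 3, 4, 5, spec)), c(12L, 21L))
  # last patch pixel closes the image when strides tile exactly
  spec2 <- split_spec(64, 64, 8, stride_rows = 8)
  expect_identical(unname(patch_to_pixel(8, 8, 8, 8, spec2)), c(64L, 64L))
  expect_error(patch_to_pixel(0, 1, 1, 1, spec), "out of range")
  expect_error(patch_to_pixel(1, 1, 65, 1, spec), "out of range")
})

test_that("overlap counts match brute-force accumulation", {
  specs <- list(split_spec(20, 30, 6, stride_rows = 2, channels = 1),
                split_spec(17, 13, 5, patch_cols = 4, stride_rows = 3,
                           stride_cols = 2, channels = 1),
                split_spec(16, 16, 8, stride_rows = 8, channels = 1))
  for (spec in specs) {
    ov <- accumulate_overlap(spec)
    brute <- matrix(0L, spec$M, spec$N)
    for (r in seq_len(spec$k1)) for (c_ in seq_len(spec$k2)) {
      rows <- (r - 1) * spec$s_x + seq_len(spec$p_x)
      cols <- (c_ - 1) * spec$s_y + seq_len(spec$p_y)
      brute[rows, cols] <- brute[rows, cols] + 1L
    }
    expect_identical(unname(ov), brute)
    expect_identical(sum(ov), spec$k1 * spec$k2 * spec$p_x * spec$p_y)
    expect_identical(ov[1, 1], 1L)
  }
  # heavy-overlap interior count is (p/s)^2
  spec <- split_spec(352, 576, 64, stride_rows = 8)
  ov <- accumulate_overlap(spec)
  expect_identical(ov[176, 288], 64L)
})

test_that("split then averaged collapse is the identity on the covered region", {
  set.seed(2)
  # integer-valued image: overlap sums and the averaging division are exact
  x <- array(as.numeric(sample(0:255, 40 * 56 * 3, replace = TRUE)),
             c(40, 56, 3))
  spec <- split_spec(40, 56, 16, stride_rows = 4, stride_cols = 8)
  back <- collapse_to_image(split_image(x, spec), spec, reduce = "average")
  ov <- accumulate_overlap(spec)
  covered <- ov > 0
  for (ch in 1:3) {
    expect_identical(back[, , ch][covered], x[, , ch][covered])
    expect_true(all(back[, , ch][!covered] == 0))
  }
})

test_that("collapsing a probability grid matches the per-pixel brute force", {
  set.seed(3)
  spec <- split_spec(24, 30, 8, stride_rows = 3, stride_cols = 5, channels = 1)
  cop <- matrix(runif(spec$k1 * spec$k2), spec$k1, spec$k2)
  got_sum <- collapse_to_image(cop, spec, reduce = "sum")
  got_avg <- collapse_to_image(cop, spec, reduce = "average")
  brute <- matrix(0, spec$M, spec$N)
  hits <- matrix(0L, spec$M, spec$N)
  for (r in seq_len(spec$k1)) for (c_ in seq_len(spec$k2)) {
    for (i in seq_len(spec$p_x)) for (j in seq_len(spec$p_y)) {
      x <- i + (r - 1) * spec$s_x
      y <- j + (c_ - 1) * spec$s_y
      brute[x, y] <- brute[x, y] + cop[r, c_]
      hits[x, y] <- hits[x, y] + 1L
    }
  }
  expect_equal(got_sum, brute, tolerance = 1e-12)
  expect_equal(got_avg, brute / pmax(hits, 1L), tolerance = 1e-12)
  # constant grid collapses to a constant plane
  flat <- collapse_to_image(matrix(0.37, spec$k1, spec$k2), spec)
  expect_equal(unique(round(flat[hits > 0], 12)), 0.37)
  expect_error(collapse_to_image(cop[-1, ], spec), "invalid geometry")
})
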