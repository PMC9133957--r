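test_that("attention maps of constant probability grids are constant", {
  spec <- split_spec(40, 48, 16, stride_rows = 4, channels = 1)
  cop <- matrix(0.3, spec$k1, spec$k2)
  ram <- build_ram(cop, spec)
  covered <- ram$overlap > 0
  expect_equal(unique(round(ram$averaged[covered], 12)), 0.3)
  expect_equal(ram$raw, 0.3 * ram$overlap, tolerance = 1e-12)
  expect_identical(dim(ram$averaged), c(40L, 48L))
})

test_that("a single positive patch lights exactly its own footprint", {
  spec <- split_spec(32, 32, 8, stride_rows = 4, channels = 1)
  cop <- matrix(0, spec$k1, spec$k2)
  cop[3, 4] <- 1
  ram <- build_ram(cop, spec)
  rows <- 2 * 4 + 1:8; cols <- 3 * 4 + 1:8
  support <- matrix(FALSE, 32, 32)
  support[rows, cols] <- TRUE
  expect_identical(unname(ram$averaged > 0), support)
  # per-pixel brute force over covering patches
  brute <- matrix(0, 32, 32)
  for (x in 1:32) for (y in 1:32) {
    num <- 0; den <- 0
    for (r in seq_len(spec$k1)) for (c_ in seq_len(spec$k2)) {
      if (x >= (r - 1) * 4 + 1 && x <= (r - 1) * 4 + 8 &&
          y >= (c_ - 1) * 4 + 1 && y <= (c_ - 1) * 4 + 8) {
        num <- num + cop[r, c_]; den <- den + 1
      }
    }
    if (den > 0) brute[x, y] <- num / den
  }
  expect_equal(unname(ram$averaged), brute, tolerance = 1e-12)
})

test_that("unit stride yields pixel-level probability resolution", {
  set.seed(12)
  spec <- split_spec(16, 16, 4, stride_rows = 1, channels = 1)
  cop <- matrix(runif(spec$k1 * spec$k2), spec$k1, spec$k2)
  ram <- build_ram(cop, spec)
  # neighbouring pixels see different covering-window sets: the map is no
  # longer block-constant
  expect_gt(length(unique(as.vector(round(ram$averaged, 10)))), 64)
})

test_that("with patch 64 and stride 8 the averaged map is 8x8-block constant", {
  set.seed(13)
  spec <- split_spec(160, 96, 64, stride_rows = 8)
  cop <- matrix(runif(spec$k1 * spec$k2), spec$k1, spec$k2)
  ram <- build_ram(cop, spec)
  blocks <- array(ram$averaged, c(8, 160 / 8, 8, 96 / 8))
  spread <- apply(blocks, c(2, 4), function(b) diff(range(b)))
  expect_true(all(spread == 0))
})

test_that("thresholding validates tau and respects coverage", {
  spec <- split_spec(30, 30, 8, stride_rows = 4, channels = 1)
  cop <- matrix(0.6, spec$k1, spec$k2)
  ram <- build_ram(cop, spec)
  expect_error(threshold_ram(ram, 1.5), "tau")
  expect_error(threshold_ram(ram, -0.1), "tau")
  m0 <- threshold_ram(ram, 0)
  expect_identical(unname(m0 == 1L), unname(ram$overlap > 0))
  m <- threshold_ram(ram, 0.5)
  expect_identical(unname(m == 1L), unname(ram$averaged >= 0.5 & ram$overlap > 0))
})

test_that("re-splitting the canonical tile yields the 44 x 72 node grid", {
  spec <- split_spec(352, 576, 64, stride_rows = 8)
  cop <- matrix(0.25, spec$k1, spec$k2)
  ram <- build_ram(cop, spec)
  x <- array(0.5, c(352, 576, 3))
  nodes <- resplit(x, ram)
  expect_identical(nodes$w, 44L)
  expect_identical(nodes$v, 72L)
  expect_identical(nodes$n, 3168L)
  expect_identical(nodes$n,
                   compute_grid(352, 8, 8) * compute_grid(576, 8, 8))
  expect_true(all(abs(nodes$cop - 0.25) < 1e-12))
  expect_error(resplit(x[1:350, , , drop = FALSE], ram), "dimensions differ")
})

test_that("node probabilities are the block means of the attention map", {
  set.seed(14)
  spec <- split_spec(48, 64, 16, stride_rows = 8, channels = 3)
  cop <- matrix(runif(spec$k1 * spec$k2), spec$k1, spec$k2)
  ram <- build_ram(cop, spec)
  x <- array(runif(48 * 64 * 3), c(48, 64, 3))
  nodes <- resplit(x, ram, node_size = 8)
  for (k in 1:8) {
    r <- sample(nodes$w, 1); c_ <- sample(nodes$v, 1)
    blk <- ram$averaged[(r - 1) * 8 + 1:8, (c_ - 1) * 8 + 1:8]
    expect_equal(nodes$cop[r, c_], mean(blk), tolerance = 1e-12)
    expect_identical(nodes$blocks[, , , r, c_],
                     x[(r - 1) * 8 + 1:8, (c_ - 1) * 8 + 1:8, ])
  }
})

test_that("node indexing is the column-major bijection", {
  w <- 6L; v <- 9L
  idx <- outer(seq_len(w), seq_len(v), function(r, c) node_index(r, c, w))
  expect_identical(sort(as.vector(idx)), seq_len(w * v))
  expect_identical(node_index(3, 2, w), 9L)  # w*(c-1)+r
})
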