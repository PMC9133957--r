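make_nodes <- function(seed = 15, w = 6L, v = 8L) {
  set.seed(seed)
  spec <- split_spec(w * 8, v * 8, 8, stride_rows = 8)
  cop <- matrix(runif(spec$k1 * spec$k2), spec$k1, spec$k2)
  x <- array(runif(w * 8 * v * 8 * 3), c(w * 8, v * 8, 3))
  resplit(x, build_ram(cop, spec), node_size = 8)
}

test_that("node features flatten 8x8x3 blocks into 192-vectors, reversibly", {
  nodes <- make_nodes()
  X <- build_node_features(nodes)
  expect_identical(dim(X), c(nodes$n, 192L))
  for (k in 1:6) {
    r <- sample(nodes$w, 1); c_ <- sample(nodes$v, 1)
    i <- node_index(r, c_, nodes$w)
    expect_identical(unflatten_node(X[i, ]), nodes$blocks[, , , r, c_])
  }
})

test_that("node histograms are normalized and match an explicit binning loop", {
  nodes <- make_nodes(16)
  H <- node_histograms(nodes)
  expect_identical(dim(H), c(nodes$n, 64L))
  expect_true(all(abs(rowSums(H) - 1) < 1e-12))
  # independent reimplementation with an explicit bin-edge loop
  blk <- nodes$blocks[, , , 2, 3]
  got <- node_histogram(blk)
  r <- as.vector(blk[, , 1]); g <- as.vector(blk[, , 2]); b <- as.vector(blk[, , 3])
  hsv <- grDevices::rgb2hsv(r = r, g = g, b = b, maxColorValue = 1)
  vals <- c(r, g, b, hsv[1, ], hsv[2, ], hsv[3, ])
  expect_length(vals, 384L)
  counts <- numeric(64)
  for (vv in vals) {
    k <- min(max(floor(vv * 64) + 1, 1), 64)
    counts[k] <- counts[k] + 1
  }
  expect_equal(got, counts / 384, tolerance = 1e-12)
  expect_equal(got, H[node_index(2, 3, nodes$w), ], tolerance = 1e-12)
})

test_that("a flat gray block concentrates its histogram in two bins", {
  blk <- array(0.5, c(8, 8, 3))  # RGB all 0.5; HSV = (0, 0, 0.5)
  h <- node_histogram(blk)
  expect_lte(sum(h > 0), 2L)
  expect_equal(sum(h), 1, tolerance = 1e-12)
})

test_that("the divergence attains its analytic limits and is symmetric", {
  q <- rep(1 / 64, 64)
  expect_equal(jsd(q, q), 0, tolerance = 1e-9)
  a <- c(rep(1 / 32, 32), rep(0, 32))
  b <- c(rep(0, 32), rep(1 / 32, 32))
  expect_equal(jsd(a, b), log(2), tolerance = 1e-6)
  set.seed(17)
  for (i in 1:20) {
    x <- runif(64); x <- x / sum(x)
    y <- runif(64); y <- y / sum(y)
    expect_lt(abs(jsd(x, y) - jsd(y, x)), 1e-12)
    expect_gte(jsd(x, y), 0)
    expect_lte(jsd(x, y), log(2) + 1e-12)
    expect_equal(jsd(x, y), jsd_oracle(x, y), tolerance = 1e-9)
  }
  expect_error(jsd(runif(64), q), "normalized")
})

test_that("adjacency construction matches the O(n^2) brute-force scan", {
  set.seed(18)
  n <- 80
  H <- matrix(runif(n * 64), n, 64)
  H <- H / rowSums(H)
  # plant some near-duplicate rows so edges exist
  for (k in seq(1, n, by = 7)) H[k + 1, ] <- H[k, ] * 0.999 + 0.001 / 64
  H <- H / rowSums(H)
  beta <- 0.02
  g <- build_adjacency(H, beta)
  brute <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (jsd_oracle(H[i, ], H[j, ]) < beta) brute[i, j] <- brute[j, i] <- 1
  }
  expect_identical(unname(as.matrix(g$adj)), brute)
  expect_gt(g$n_edges, 0)
  # A-hat is symmetric with non-negative entries
  ah <- as.matrix(g$a_hat)
  expect_equal(ah, t(ah), tolerance = 1e-12)
  expect_true(all(ah >= 0))
})

test_that("identical nodes form a complete graph with uniform propagation", {
  n <- 12
  H <- matrix(rep(c(rep(0.5 / 16, 16), rep(0.5 / 48, 48)), n), n, 64,
              byrow = TRUE)
  g <- build_adjacency(H, 0.005)
  A <- as.matrix(g$adj)
  expect_identical(unname(A), matrix(1, n, n) - diag(n))
  expect_equal(unname(as.matrix(g$a_hat)), matrix(1 / n, n, n),
               tolerance = 1e-12)
  # distinct nodes at vanishing threshold: no edges, identity propagation
  set.seed(19)
  H2 <- matrix(runif(10 * 64), 10, 64); H2 <- H2 / rowSums(H2)
  g2 <- build_adjacency(H2, 1e-9)
  expect_identical(g2$n_edges, 0L)
  expect_equal(unname(as.matrix(g2$a_hat)), diag(10), tolerance = 1e-12)
  expect_error(build_adjacency(H2, 0), "beta")
})

test_that("the forward pass follows the three-layer propagation form", {
  # hand-computed two-node example, bias-free
  a_hat <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  X <- matrix(c(1, 0, 0, 1), 2, 2)
  W0 <- matrix(c(1, -1, 2, 0), 2, 2)
  W1 <- diag(2)
  W2 <- matrix(c(1, 0, 0, 1), 2, 2)
  # layer 1: A X = [[.5,.5],[.5,.5]]; (A X) W0 = [[0,1],[0,1]]; relu same
  # layer 2: A H = [[0,1],[0,1]]; W1 identity; relu same
  # layer 3: A H = [[0,1],[0,1]]; logits [[0,1],[0,1]]
  Z <- gcn_forward(X, a_hat, list(W0, W1, W2))
  e <- exp(1)
  expected <- matrix(rep(c(1 / (1 + e), e / (1 + e)), each = 2), 2, 2)
  expect_equal(Z, expected, tolerance = 1e-12)
  expect_true(all(abs(rowSums(Z) - 1) < 1e-5))
  # dimension chain: k -> u1 -> u2 -> c must multiply through
  expect_error(gcn_forward(X, a_hat, list(matrix(0, 3, 2))),
               "dimension mismatch")
})

test_that("softmax output is row-stochastic for arbitrary weights", {
  set.seed(20)
  nodes <- make_nodes(21)
  X <- build_node_features(nodes)
  g <- build_adjacency(node_histograms(nodes), 0.05)
  W <- list(matrix(rnorm(192 * 64, sd = 0.3), 192, 64),
            matrix(rnorm(64 * 32, sd = 0.3), 64, 32),
            matrix(rnorm(32 * 2, sd = 0.3), 32, 2))
  Z <- gcn_forward(X, g, W)
  expect_identical(dim(Z), c(nodes$n, 2L))
  expect_true(all(abs(rowSums(Z) - 1) < 1e-5))
  # single node, unit propagation, zero weights -> uniform
  Z1 <- gcn_forward(matrix(1, 1, 4), matrix(1, 1, 1),
                    list(matrix(0, 4, 3)))
  expect_equal(Z1, matrix(1 / 3, 1, 3), tolerance = 1e-12)
})

test_that("training separates noisy two-cluster pseudo-labels", {
  set.seed(22)
  n <- 60
  truth <- rep(c("negative", "positive"), each = n / 2)
  # two tight histogram clusters -> within-cluster edges only
  base1 <- c(rep(0.8 / 8, 8), rep(0.2 / 56, 56))
  base2 <- c(rep(0.2 / 56, 56), rep(0.8 / 8, 8))
  H <- t(vapply(seq_len(n), function(i) {
    b <- if (truth[i] == "negative") base1 else base2
    b <- b + runif(64, 0, 1e-4)
    b / sum(b)
  }, numeric(64)))
  g <- build_adjacency(H, 0.01)
  X <- cbind(as.numeric(truth == "positive") + rnorm(n, sd = 0.05),
             rnorm(n, sd = 0.05))
  noisy <- truth
  flip <- sample(n, n * 0.1)
  noisy[flip] <- ifelse(truth[flip] == "positive", "negative", "positive")
  m <- train_gcn(X, g, factor(noisy, levels = c("negative", "positive")),
                 hidden = c(8), epochs = 150, seed = 3)
  acc <- mean((m$Z[, 2] >= 0.5) == (truth == "positive"))
  expect_gte(acc, 0.95)
  expect_lte(tail(m$loss, 1), m$loss[1])
})

test_that("degenerate or zero-epoch training falls through unchanged", {
  nodes <- make_nodes(23)
  expect_identical(refine(nodes, epochs = 0), nodes)
  X <- build_node_features(nodes)
  g <- build_adjacency(node_histograms(nodes), 0.05)
  expect_warning(
    m <- train_gcn(X, g, factor(rep("negative", nodes$n),
                                levels = c("negative", "positive"))),
    "degenerate")
  expect_false(m$trained)
  expect_true(all(abs(rowSums(m$Z) - 1) < 1e-5))
})

test_that("an isolated positive among identical negatives is pulled down", {
  # all nodes share one colour: complete graph; a single positive seed in a
  # sea of identical negatives cannot be fit and moves toward its neighbours
  w <- 4L; v <- 6L
  spec <- split_spec(w * 8, v * 8, 8, stride_rows = 8)
  x <- array(0.4, c(w * 8, v * 8, 3))
  cop <- matrix(0.01, spec$k1, spec$k2)
  cop[2, 2] <- 0.95
  nodes <- resplit(x, build_ram(cop, spec), node_size = 8)
  ref <- refine(nodes, consistency = FALSE, epochs = 80, seed = 4)
  i <- node_index(2, 2, nodes$w)
  expect_lt(as.vector(ref$cop)[i], as.vector(nodes$cop)[i])
})

test_that("seed construction screens candidates by block class and context", {
  can <- small_canopy(seed = 31, n_lesions = 2)
  clf <- oracle_patch_classifier()
  spec <- split_spec(96, 144, 64, stride_rows = 8)
  cop <- classify_configuration(split_image(can$image, spec), clf)
  nodes <- resplit(can$image, build_ram(cop, spec))
  g <- build_adjacency(node_histograms(nodes), 0.03)
  lab <- pseudo_labels(nodes, g, clf)
  gt1 <- gt_node_set(can$mask, min_pixels = 1)
  pos <- which(lab == "positive")
  expect_gt(length(pos), 0)
  expect_true(all(pos %in% gt1))
  expect_gt(sum(lab == "negative", na.rm = TRUE), 0)
  # doubling admits exactly as many extra, lower-probability nodes
  lab2 <- pseudo_labels(nodes, g, clf, double_positive_nodes = TRUE)
  expect_identical(sum(lab2 == "positive", na.rm = TRUE), 2L * length(pos))
})
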