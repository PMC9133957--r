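#' Node feature matrix
#'
#' Flattens every `node_size x node_size x 3` block of a [resplit()] node
#' grid into a length-`k` vector (`k = 192` for 8 px nodes) and stacks
#' them into an `n x k` matrix. Row `i` corresponds to grid cell `(r, c)`
#' via the column-major index `idx = w * (c - 1) + r` (see
#' [node_index()]); flattening uses R's native column-major order, and
#' [unflatten_node()] is its exact inverse.
#'
#' @param nodes A `node_grid` from [resplit()].
#' @return `n x k` numeric matrix of raw pixel features in `[0, 1]`.
#' @export
build_node_features <- function(nodes) {
  stopifnot(inherits(nodes, "node_grid"))
  k <- nodes$node_size^2 * dim(nodes$blocks)[3]
  t(matrix(nodes$blocks, nrow = k))
}

#' @rdname build_node_features
#' @param x A feature row (length `k` vector).
#' @param node_size Block side length.
#' @param channels Channel count.
#' @export
unflatten_node <- function(x, node_size = 8L, channels = 3L) {
  array(x, c(node_size, node_size, channels))
}

#' Colour-histogram node descriptor
#'
#' A non-parametric colour signature per node: the block's pixel values in
#' RGB are concatenated with their HSV transform (all channels on the
#' `[0, 1]` scale, so hue is rescaled to the common value range), and the
#' resulting `2 * 3 * node_size^2` values (384 for 8 px nodes) are binned
#' into a 64-bin equal-width histogram over `[0, 1]`, normalized to sum 1.
#'
#' @param block A `node_size x node_size x 3` RGB array in `[0, 1]`.
#' @param bins Number of histogram bins.
#' @return Length-`bins` probability vector.
#' @export
node_histogram <- function(block, bins = 64L) {
  block <- as_image_array(block)
  node_histograms_features(matrix(as.vector(block), nrow = 1L), bins)[1L, ]
}

# Histogram every row of an n x 192 feature matrix (column-major RGB).
node_histograms_features <- function(X, bins = 64L) {
  npix <- ncol(X) %/% 3L
  R <- X[, seq_len(npix), drop = FALSE]
  G <- X[, npix + seq_len(npix), drop = FALSE]
  B <- X[, 2L * npix + seq_len(npix), drop = FALSE]
  hsv <- grDevices::rgb2hsv(r = as.vector(t(R)), g = as.vector(t(G)),
                            b = as.vector(t(B)), maxColorValue = 1)
  n <- nrow(X)
  H <- matrix(hsv[1L, ], n, npix, byrow = TRUE)
  S <- matrix(hsv[2L, ], n, npix, byrow = TRUE)
  V <- matrix(hsv[3L, ], n, npix, byrow = TRUE)
  vals <- cbind(X, H, S, V)
  idx <- pmin(pmax(floor(vals * bins) + 1L, 1L), bins)
  out <- t(vapply(seq_len(n), function(i) tabulate(idx[i, ], nbins = bins),
                  numeric(bins)))
  out / ncol(vals)
}

#' @rdname node_histogram
#' @param nodes A `node_grid`.
#' @return For `node_histograms()`: `n x bins` matrix, rows in node-index
#'   order.
#' @export
node_histograms <- function(nodes, bins = 64L) {
  node_histograms_features(build_node_features(nodes), bins)
}

#' Jensen-Shannon divergence between two histograms
#'
#' `JSD(q_i, q_j) = 0.5 KL(q_i || m) + 0.5 KL(q_j || m)` with
#' `m = (q_i + q_j) / 2`, natural logarithm. The divergence is symmetric —
#' the property that makes it suitable for building a symmetric adjacency
#' matrix — and bounded in `[0, log 2]`, attaining the upper bound for
#' histograms with disjoint support. Zero-count bins are handled by adding
#' a small epsilon to both histograms and renormalizing, keeping the KL
#' terms finite.
#'
#' @param q_i,q_j Probability vectors of equal length summing to 1.
#' @param eps Smoothing constant.
#' @return Scalar divergence in `[0, log 2]`.
#' @export
jsd <- function(q_i, q_j, eps = 1e-12) {
  if (length(q_i) != length(q_j)) {
    stop("histograms must have equal length", call. = FALSE)
  }
  if (abs(sum(q_i) - 1) > 1e-6 || abs(sum(q_j) - 1) > 1e-6 ||
      any(q_i < 0) || any(q_j < 0)) {
    stop("histograms must be normalized probability vectors", call. = FALSE)
  }
  p <- (q_i + eps) / sum(q_i + eps)
  q <- (q_j + eps) / sum(q_j + eps)
  m <- 0.5 * (p + q)
  0.5 * sum(p * log(p / m)) + 0.5 * sum(q * log(q / m))
}

#' Build the JSD similarity graph of a node grid
#'
#' Connects nodes `i != j` by an edge when the Jensen-Shannon divergence
#' between their colour histograms falls below `beta`, giving a symmetric
#' zero-diagonal adjacency `Adj`. Self-loops are then added
#' (`A = Adj + I`, nodes being self-similar) and the propagation matrix is
#' symmetrically normalized by the degree matrix:
#' `A_hat = D^{-1/2} A D^{-1/2}` with `D_ii = sum_j A_ij` — the first-order
#' spectral graph convolution operator.
#'
#' The default `beta = 0.005` is deliberately strict: under natural texture
#' variation only near-identical nodes connect, so positive evidence
#' propagates within colour-coherent regions without leaking across them.
#'
#' @param hists `n x bins` matrix of node histograms
#'   (see [node_histograms()]), or a `node_grid` from which histograms are
#'   computed.
#' @param beta Edge threshold on the divergence; must be positive.
#' @param eps Histogram smoothing constant.
#' @return An object of class `patch_graph` with sparse `adj` and `a_hat`
#'   (Matrix package), `n`, `n_edges` and `beta`.
#' @export
build_adjacency <- function(hists, beta = 0.005, eps = 1e-12) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0) {
    stop("beta must be a positive scalar", call. = FALSE)
  }
  if (inherits(hists, "node_grid")) hists <- node_histograms(hists)
  n <- nrow(hists)
  Q <- (hists + eps) / rowSums(hists + eps)
  edges <- jsd_edge_scan(Q, beta)
  if (nrow(edges) > 0L) {
    adj <- Matrix::sparseMatrix(i = c(edges[, 1L], edges[, 2L]),
                                j = c(edges[, 2L], edges[, 1L]),
                                x = 1, dims = c(n, n))
  } else {
    adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n))
  }
  a <- adj + Matrix::Diagonal(n)
  dinv <- 1 / sqrt(Matrix::rowSums(a))
  a_hat <- Matrix::Diagonal(x = dinv) %*% a %*% Matrix::Diagonal(x = dinv)
  structure(list(adj = adj, a_hat = a_hat, n = n,
                 n_edges = nrow(edges), beta = beta),
            class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("patch_graph: %d nodes, %d edges (beta = %g)\n",
              x$n, x$n_edges, x$beta))
  invisible(x)
}

#' Write a graph as plain-text edge list
#'
#' @param graph A `patch_graph`.
#' @param path Output path; one `i j` pair per line, 1-based.
#' @return `path`, invisibly.
#' @export
export_edges <- function(graph, path) {
  idx <- Matrix::which(graph$adj != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  utils::write.table(idx, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

gcn_init_weights <- function(sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(length(sizes) - 1L), function(t) {
    fin <- sizes[t]; fout <- sizes[t + 1L]
    s <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -s, s), fin, fout)
  })
}

#' Graph convolutional forward pass
#'
#' The layer recursion `H^(t+1) = relu(A_hat H^(t) W^(t))` starting from
#' the node features `H^(0) = X`, with a row-wise softmax after the last
#' (activation-free) layer:
#' `Z = softmax(A_hat relu(A_hat relu(A_hat X W0) W1) W2)` for the 3-layer
#' network. Rows of `Z` are probability vectors over the node classes.
#'
#' @param X `n x k` node feature matrix.
#' @param graph A `patch_graph` (or a plain propagation matrix).
#' @param weights List of weight matrices `W^(t)`, dims chained
#'   `k -> u_1 -> ... -> c`.
#' @param bias Optional list of per-layer bias vectors (`NULL` for the
#'   pure propagation form).
#' @return `n x c` row-stochastic matrix `Z`.
#' @export
gcn_forward <- function(X, graph, weights, bias = NULL) {
  a_hat <- if (inherits(graph, "patch_graph")) graph$a_hat else graph
  H <- X
  L <- length(weights)
  for (t in seq_len(L)) {
    if (ncol(H) != nrow(weights[[t]])) {
      stop(sprintf("dimension mismatch: layer %d expects %d inputs, got %d",
                   t, nrow(weights[[t]]), ncol(H)), call. = FALSE)
    }
    H <- as.matrix(a_hat %*% H) %*% weights[[t]]
    if (!is.null(bias)) H <- sweep(H, 2L, bias[[t]], "+")
    if (t < L) H <- pmax(H, 0)
  }
  row_softmax(H)
}

#' Train the refinement GCN on pseudo-labels
#'
#' Minimizes the cross-entropy `-sum_{i in I} sum_l Y_il log Z_il` over the
#' labeled node set `I` with Adam. Nodes marked `NA` are unlabeled — the
#' transductive setting of first-order graph convolution — and contribute
#' to the loss only through propagation. With `class_balance` set, the
#' labeled loss is reweighted so the positive (last) class carries that
#' share of it; lesion nodes are typically under 1% of a canopy grid, and
#' an unweighted loss lets the majority term swamp them. Layers carry bias
#' vectors (disable with `use_bias = FALSE` for the strictly bias-free
#' propagation form).
#'
#' @param X `n x k` node feature matrix.
#' @param graph A `patch_graph`.
#' @param labels Factor/character node labels (length `n`, `NA` =
#'   unlabeled), or an `n x c` one-hot matrix with all-zero rows for
#'   unlabeled nodes.
#' @param hidden Hidden-layer widths; `c(64, 32)` gives the 3-layer
#'   network, `64` the 2-layer variant.
#' @param epochs Training epochs; `0` returns the freshly initialized
#'   model untouched.
#' @param lr Adam learning rate.
#' @param patience,min_delta Early-stopping controls on the training loss.
#' @param class_balance Share of the loss carried by the last class
#'   (`NULL` = plain unweighted mean over labeled nodes).
#' @param use_bias Include per-layer bias vectors.
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `gcn_model` with `weights`, `bias`, `Z`
#'   (final node probabilities), `loss` history and layer sizes.
#' @export
train_gcn <- function(X, graph, labels, hidden = c(64, 32), epochs = 200,
                      lr = 0.01, patience = 200, min_delta = 1e-4,
                      class_balance = NULL, use_bias = TRUE, seed = NULL) {
  n <- nrow(X)
  if (is.matrix(labels)) {
    Y <- labels
  } else {
    lf <- as.factor(labels)
    Y <- matrix(0, n, max(2L, nlevels(lf)))
    lab <- which(!is.na(lf))
    Y[cbind(lab, as.integer(lf[lab]))] <- 1
  }
  cls <- ncol(Y)
  counts <- colSums(Y)
  if (sum(counts > 0) < 2L) {
    warning("degenerate pseudo-labeling: all labeled nodes share one class; skipping training")
    w <- gcn_init_weights(c(ncol(X), hidden, cls), seed)
    return(structure(list(weights = w, bias = NULL,
                          Z = gcn_forward(X, graph, w),
                          loss = numeric(0), trained = FALSE,
                          hidden = hidden), class = "gcn_model"))
  }
  weights <- gcn_init_weights(c(ncol(X), hidden, cls), seed)
  bias <- if (use_bias) lapply(c(hidden, cls), function(u) rep(0, u))
  a_hat <- graph$a_hat
  if (epochs < 1L) {
    return(structure(list(weights = weights, bias = bias,
                          Z = gcn_forward(X, graph, weights, bias),
                          loss = numeric(0), trained = FALSE,
                          hidden = hidden), class = "gcn_model"))
  }
  # per-node loss weights over the labeled set
  mask <- numeric(n)
  lab_idx <- which(rowSums(Y) > 0)
  if (is.null(class_balance)) {
    mask[lab_idx] <- 1 / length(lab_idx)
  } else {
    pos <- Y[, cls] > 0
    mask[pos] <- class_balance / max(sum(pos), 1L)
    neg <- rowSums(Y) > 0 & !pos
    mask[neg] <- (1 - class_balance) / max(sum(neg), 1L)
  }
  L <- length(weights)
  opt <- lapply(weights, function(w) list(m = w * 0, v = w * 0))
  optb <- if (use_bias) lapply(bias, function(b) list(m = b * 0, v = b * 0))
  best <- list(loss = Inf, weights = weights, bias = bias)
  wait <- 0L; losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    AH <- vector("list", L)   # A_hat %*% H^(t-1)
    Zpre <- vector("list", L)
    H <- X
    for (t in seq_len(L)) {
      AH[[t]] <- as.matrix(a_hat %*% H)
      Zpre[[t]] <- AH[[t]] %*% weights[[t]]
      if (use_bias) Zpre[[t]] <- sweep(Zpre[[t]], 2L, bias[[t]], "+")
      H <- if (t < L) pmax(Zpre[[t]], 0) else Zpre[[t]]
    }
    P <- row_softmax(H)
    loss <- -sum(mask * rowSums(Y * log(pmax(P, 1e-12))))
    losses <- c(losses, loss)
    delta <- (P - Y) * mask
    grads <- vector("list", L)
    gradb <- vector("list", L)
    for (t in rev(seq_len(L))) {
      grads[[t]] <- crossprod(AH[[t]], delta)
      gradb[[t]] <- colSums(delta)
      if (t > 1L) {
        delta <- as.matrix(a_hat %*% (delta %*% t(weights[[t]])))
        delta <- delta * (Zpre[[t - 1L]] > 0)
      }
    }
    for (t in seq_len(L)) {
      up <- adam_step(weights[[t]], grads[[t]], opt[[t]], lr, ep)
      weights[[t]] <- up$par; opt[[t]] <- up$state
      if (use_bias) {
        up <- adam_step(bias[[t]], gradb[[t]], optb[[t]], lr, ep)
        bias[[t]] <- up$par; optb[[t]] <- up$state
      }
    }
    if (loss < best$loss - min_delta) {
      best <- list(loss = loss, weights = weights, bias = bias)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(weights = best$weights, bias = best$bias,
                 Z = gcn_forward(X, graph, best$weights, best$bias),
                 loss = losses, trained = TRUE, hidden = hidden),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("gcn_model: %d layers (hidden: %s), %s\n",
              length(x$weights), paste(x$hidden, collapse = ", "),
              if (x$trained) sprintf("trained %d epochs, final loss %.4f",
                                     length(x$loss), min(x$loss))
              else "untrained"))
  invisible(x)
}

#' Derive transductive pseudo-labels from node probabilities
#'
#' Builds the labeled node set for GCN refinement from the attention-map
#' node scores. The overlap-averaged attention cone is spatially smooth,
#' so around each detection (each local maximum of the node-score surface
#' reaching `min_peak`) the candidate positives are the nodes scoring at
#' least `high` times that local peak; anchoring to local peaks rather
#' than one global cut keeps weaker lesions seeded, and anchoring
#' relatively absorbs backbone-dependent confidence scales. Nodes at or
#' below `low` times the global peak become negative seeds; the mid band
#' — the smeared skirt of the cone, whose class is genuinely ambiguous —
#' stays unlabeled.
#'
#' Candidate positives are then screened twice:
#' \itemize{
#' \item Decomposition-principle validation (when a `classifier` is
#'   given): the same classifier that scored the 64 px patches is applied
#'   to each candidate's own rescaled node block. A canopy crop shares
#'   the feature statistics of the whole, so a node that truly carries
#'   lesion colour classifies as lesion at node scale too, while a node
#'   that merely sits near a lesion — inheriting its attention smear —
#'   classifies as healthy background and is demoted.
#' \item Neighbourhood consistency (when a `graph` is given): positives
#'   whose similarity neighbours are mostly non-positive are demoted to
#'   unlabeled, iterating to a fixed point — such nodes are
#'   colour-indistinguishable from background, so their label cannot be
#'   fit without dragging background along.
#' }
#'
#' @param nodes A `node_grid` from [resplit()], or a plain numeric matrix
#'   of node scores (then no block validation is possible).
#' @param graph The node similarity `patch_graph` (used by the
#'   consistency filter; `NULL` skips it).
#' @param classifier A `patch_classifier` for block validation (`NULL`
#'   skips it).
#' @param high Candidate threshold as a fraction of the local peak score.
#' @param low Negative-seed threshold as a fraction of the global peak.
#' @param min_peak Minimum absolute score for a local maximum to count as
#'   a detection.
#' @param window Half-width, in nodes, of the local-maximum window
#'   (default 8 nodes = one patch width at the canonical geometry).
#' @param consistency Apply the neighbourhood-consistency demotion.
#' @param double_positive_nodes If `TRUE`, the positive seed set is
#'   doubled by admitting the equally many next-most-probable non-seed
#'   nodes (the node-doubling ablation variant: the extra nodes have
#'   lower probability of truly being lesion).
#' @return Factor of length `n` with levels `negative`, `positive` and
#'   `NA` for unlabeled nodes.
#' @export
pseudo_labels <- function(nodes, graph = NULL, classifier = NULL,
                          high = 0.75, low = 0.1, min_peak = 0.5,
                          window = 8L, consistency = TRUE,
                          double_positive_nodes = FALSE) {
  if (high < low) stop("high must be >= low", call. = FALSE)
  grid <- inherits(nodes, "node_grid")
  P <- if (grid) nodes$cop else as.matrix(nodes)
  w <- nrow(P); v <- ncol(P)
  p <- as.vector(P)
  # candidates: near-peak nodes around each local maximum of the score
  cand <- matrix(FALSE, w, v)
  for (i in seq_len(w)) for (j in seq_len(v)) {
    if (P[i, j] < min_peak) next
    wi <- max(1L, i - window):min(w, i + window)
    wj <- max(1L, j - window):min(v, j + window)
    if (P[i, j] >= max(P[wi, wj])) {
      cand[wi, wj] <- cand[wi, wj] | (P[wi, wj] >= high * P[i, j])
    }
  }
  cand <- which(as.vector(cand))
  if (!is.null(classifier) && grid && length(cand)) {
    blocks <- lapply(cand, function(i) {
      rc <- arrayInd(i, c(w, v))
      nodes$blocks[, , , rc[1L], rc[2L]]
    })
    pv <- predict(classifier, blocks)
    cand <- cand[pv[, ncol(pv)] >= 0.5]
  }
  lab <- rep(NA_character_, length(p))
  lab[p <= low * max(p)] <- "negative"
  lab[cand] <- "positive"
  if (consistency && !is.null(graph)) {
    adj <- graph$adj
    repeat {
      posi <- which(lab == "positive")
      if (!length(posi)) break
      is_pos <- !is.na(lab) & lab == "positive"
      nb_pos <- as.vector(adj[posi, , drop = FALSE] %*% is_pos)
      nb_all <- as.vector(Matrix::rowSums(adj[posi, , drop = FALSE]))
      bad <- nb_all > 0 & nb_pos < 0.5 * nb_all
      if (!any(bad)) break
      lab[posi[bad]] <- NA_character_
    }
  }
  if (double_positive_nodes) {
    m <- sum(lab == "positive", na.rm = TRUE)
    extra_pool <- which(is.na(lab) | lab == "negative")
    if (m > 0L && length(extra_pool)) {
      extra <- extra_pool[order(p[extra_pool], decreasing = TRUE)]
      extra <- extra[seq_len(min(m, length(extra)))]
      lab[extra] <- "positive"
    }
  }
  factor(lab, levels = c("negative", "positive"))
}

#' Refine node probabilities with the similarity-graph GCN
#'
#' The refinement step: build histogram features and the JSD similarity
#' graph for a node grid, derive transductive pseudo-labels from the node
#' scores (see [pseudo_labels()]), train the GCN on them, and replace the
#' node probabilities with the positive-class column of the trained
#' network's output `Z`. The network sees each node's raw pixels plus the
#' colour-similarity structure, so probability mass moves between nodes
#' that look alike — sharpening the smeared attention footprint onto the
#' nodes that actually carry lesion colour.
#'
#' If the seeds end up single-class the refinement is skipped with a
#' warning and the grid is returned unchanged; likewise `epochs = 0` is an
#' exact passthrough.
#'
#' @param nodes A `node_grid` from [resplit()].
#' @param classifier The `patch_classifier` used for the attention map;
#'   when given, candidate seeds are validated by classifying their own
#'   node blocks (see [pseudo_labels()]).
#' @param beta JSD edge threshold (see [build_adjacency()]; the default is
#'   the reference operating point for dark homogeneous canopies —
#'   [calibrate_beta()] adapts it to a dataset).
#' @param label_high,label_low Seed thresholds on node probabilities,
#'   relative to the local/global peak score (see [pseudo_labels()]).
#' @param hidden,epochs,lr,patience,min_delta,seed GCN training controls
#'   (see [train_gcn()]).
#' @param class_balance Positive-class share of the training loss.
#' @param min_peak Detection floor: local score maxima below this seed
#'   nothing, and when the whole grid stays below it the grid is returned
#'   unchanged — with no confident detection there is nothing to sharpen,
#'   and seeding off a noise peak would hallucinate lesions.
#' @param consistency Neighbourhood-consistency seed filtering.
#' @param double_positive_nodes Node-doubling ablation switch.
#' @param graph Optionally a precomputed `patch_graph` for this grid
#'   (avoids recomputing histograms across ablation variants).
#' @return The refined `node_grid`; the fitted `gcn_model`, the
#'   `patch_graph` and the seed labels are attached as fields `model`,
#'   `graph` and `labels`.
#' @export
refine <- function(nodes, classifier = NULL, beta = 0.005,
                   label_high = 0.75, label_low = 0.1,
                   hidden = c(64, 32), epochs = 200, lr = 0.01,
                   patience = 200, min_delta = 1e-4, seed = NULL,
                   class_balance = 0.3, min_peak = 0.5,
                   consistency = TRUE,
                   double_positive_nodes = FALSE, graph = NULL) {
  stopifnot(inherits(nodes, "node_grid"))
  if (epochs < 1L) return(nodes)
  p <- as.vector(nodes$cop)
  if (max(p) < min_peak) return(nodes)
  X <- build_node_features(nodes)
  if (is.null(graph)) graph <- build_adjacency(node_histograms_features(X), beta)
  labels <- pseudo_labels(nodes, graph, classifier,
                          high = label_high, low = label_low,
                          min_peak = min_peak, consistency = consistency,
                          double_positive_nodes = double_positive_nodes)
  if (nlevels(droplevels(labels[!is.na(labels)])) < 2L) {
    warning("degenerate pseudo-labeling: seeds are single-class; returning grid unchanged")
    return(nodes)
  }
  model <- train_gcn(X, graph, labels, hidden = hidden, epochs = epochs,
                     lr = lr, patience = patience, min_delta = min_delta,
                     class_balance = class_balance, seed = seed)
  refined <- nodes
  refined$cop <- matrix(model$Z[, 2L], nodes$w, nodes$v)
  refined$model <- model
  refined$graph <- graph
  refined$labels <- labels
  refined
}

#' Calibrate the JSD edge threshold for a dataset
#'
#' The edge threshold is dataset-specific: it must fall between the
#' divergence of same-surface node pairs and the divergence separating
#' lesion-tinged nodes from background. This helper places it at a fixed
#' quantile of the pairwise-divergence distribution of sampled node pairs
#' — a one-shot per-dataset calibration of the graph's operating point.
#'
#' @param hists Node histogram matrix (or a `node_grid`).
#' @param quantile Pairwise-JSD quantile to use.
#' @param n_pairs Number of sampled pairs.
#' @param eps Histogram smoothing constant.
#' @return Scalar threshold.
#' @export
calibrate_beta <- function(hists, quantile = 0.01, n_pairs = 2000L,
                           eps = 1e-12) {
  if (inherits(hists, "node_grid")) hists <- node_histograms(hists)
  n <- nrow(hists)
  Q <- (hists + eps) / rowSums(hists + eps)
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n, n_pairs, replace = TRUE)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  M <- 0.5 * (Q[i, , drop = FALSE] + Q[j, , drop = FALSE])
  js <- 0.5 * rowSums(Q[i, , drop = FALSE] *
                        log(Q[i, , drop = FALSE] / M)) +
        0.5 * rowSums(Q[j, , drop = FALSE] *
                        log(Q[j, , drop = FALSE] / M))
  as.numeric(stats::quantile(js, quantile))
}
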