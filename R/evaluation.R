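#' Patch-based Dice and IoU
#'
#' Segmentation agreement measured on node (super-pixel) sets rather than
#' pixels: with `X` the selected ground-truth node set and `Y` the
#' predicted node set, `DSC_patch = 2 |X ∩ Y| / (|X| + |Y|)` and
#' `IoU = |X ∩ Y| / |X ∪ Y|`. Because nodes are uniform blocks, these
#' equal the pixel-level Dice/IoU of the corresponding block masks. Both
#' metrics are defined as 1 when both sets are empty (a correctly
#' predicted lesion-free image), and satisfy `DSC = 2 IoU / (1 + IoU)`.
#'
#' @param selected Integer vector of ground-truth node indices.
#' @param predicted Integer vector of predicted node indices.
#' @return Scalar in `[0, 1]`.
#' @export
dsc_patch <- function(selected, predicted) {
  selected <- unique(as.integer(selected))
  predicted <- unique(as.integer(predicted))
  if (length(selected) == 0L && length(predicted) == 0L) return(1)
  2 * length(intersect(selected, predicted)) /
    (length(selected) + length(predicted))
}

#' @rdname dsc_patch
#' @export
iou_patch <- function(selected, predicted) {
  selected <- unique(as.integer(selected))
  predicted <- unique(as.integer(predicted))
  if (length(selected) == 0L && length(predicted) == 0L) return(1)
  length(intersect(selected, predicted)) /
    length(union(selected, predicted))
}

#' Ground-truth and predicted node sets
#'
#' `gt_node_set()` selects the nodes of a pixel ground-truth mask that an
#' annotator would mark: those containing at least `min_pixels` lesion
#' pixels (a 1 px sliver is not a visible lesion patch). Node indices are
#' column-major over the node grid, matching [build_node_features()] row
#' order. `predicted_node_set()` thresholds a node grid's probabilities.
#'
#' @param mask Logical/0-1 pixel mask with dims divisible by `node_size`.
#' @param node_size Node side length in pixels.
#' @param min_pixels Minimum lesion pixels for a node to count as
#'   ground-truth positive.
#' @return Integer vector of node indices.
#' @export
gt_node_set <- function(mask, node_size = 8L, min_pixels = 4L) {
  M <- nrow(mask); N <- ncol(mask)
  stopifnot(M %% node_size == 0L, N %% node_size == 0L)
  w <- M %/% node_size; v <- N %/% node_size
  m <- array(as.numeric(mask), c(node_size, w, node_size, v))
  counts <- apply(m, c(2L, 4L), sum)
  which(as.vector(counts) >= min_pixels)
}

#' @rdname gt_node_set
#' @param nodes A `node_grid`.
#' @param threshold Probability cut.
#' @export
predicted_node_set <- function(nodes, threshold = 0.5) {
  which(as.vector(nodes$cop) >= threshold)
}

#' Ablation harness over refinement variants
#'
#' Runs the segmentation variants on a set of synthetic canopies and
#' reports mean patch-level Dice/IoU per variant against the exact ground
#' truth:
#' \describe{
#'   \item{`ram`}{thresholding the overlap-averaged attention map (no
#'     graph refinement);}
#'   \item{`gcn2`}{2-layer GCN refinement;}
#'   \item{`gcn3`}{3-layer GCN refinement (the default pipeline);}
#'   \item{`gcn3_double`}{3-layer GCN with the positive pseudo-label node
#'     set doubled by admitting the next-most-probable (hence less
#'     reliable) nodes.}
#' }
#' Per-image artifacts that are shared across variants — the patch split,
#' classification, attention map, node grid, histograms and similarity
#' graph — are computed once.
#'
#' @param canopies List of `synthetic_canopy` objects (see
#'   [generate_canopy()]).
#' @param classifier A `patch_classifier`.
#' @param variants Subset of the variants above.
#' @param config A [seg_config()].
#' @return Data frame with one row per variant (`variant`, `dsc`, `iou`),
#'   with per-image metrics attached as attribute `"per_image"`.
#' @export
run_ablation <- function(canopies, classifier,
                         variants = c("ram", "gcn2", "gcn3", "gcn3_double"),
                         config = seg_config()) {
  variants <- match.arg(variants, several.ok = TRUE)
  rows <- list()
  for (img_i in seq_along(canopies)) {
    can <- canopies[[img_i]]
    spec <- split_spec(nrow(can$mask), ncol(can$mask), config$patch_size,
                       stride_rows = config$stride)
    co <- split_image(can$image, spec)
    cop <- classify_configuration(co, classifier, class = config$class)
    ram <- build_ram(cop, spec)
    nodes <- resplit(can$image, ram, config$node_size)
    gt <- gt_node_set(can$mask, config$node_size, config$gt_min_pixels)
    if (!is.null(config$seed)) set.seed(config$seed + img_i)
    hists <- node_histograms(nodes)
    beta <- config$beta
    if (is.null(beta)) beta <- calibrate_beta(hists, config$beta_quantile)
    graph <- build_adjacency(hists, beta)
    ref_args <- list(nodes, classifier = classifier, graph = graph,
                     label_high = config$label_high,
                     label_low = config$label_low,
                     min_peak = config$min_peak,
                     class_balance = config$class_balance,
                     consistency = config$consistency,
                     epochs = config$epochs, lr = config$lr,
                     seed = config$seed + img_i)
    for (va in variants) {
      ref <- switch(va,
        ram = nodes,
        gcn2 = do.call(refine, c(ref_args, list(hidden = config$hidden[1]))),
        gcn3 = do.call(refine, c(ref_args, list(hidden = config$hidden))),
        gcn3_double = do.call(refine, c(ref_args,
                                        list(hidden = config$hidden,
                                             double_positive_nodes = TRUE))))
      pred <- predicted_node_set(ref, config$tau)
      rows[[length(rows) + 1L]] <- data.frame(
        image = img_i, variant = va,
        dsc = dsc_patch(gt, pred), iou = iou_patch(gt, pred))
    }
  }
  per_image <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(per_image, per_image$variant), function(d) {
    data.frame(variant = d$variant[1], dsc = mean(d$dsc), iou = mean(d$iou))
  }))
  out <- out[match(variants, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_image") <- per_image
  out
}

#' Write an ablation (or any metric) table as CSV
#'
#' @param table Data frame of metrics.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
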