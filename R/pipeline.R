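#' Pipeline configuration
#'
#' Bundles the tunable parameters of the end-to-end segmentation pipeline.
#' Defaults are the canopy operating point: 64 px patches with a hard
#' stride of 8 (64-fold overlap per pixel in the interior), decision
#' threshold 0.5, 8 px nodes, JSD edge threshold 0.03 (the synthetic
#' canopy's operating point; the reference value for dark homogeneous
#' real canopies is 0.005), and a 3-layer GCN (hidden widths 64 and 32)
#' trained with Adam at learning rate 0.01 for up to 200 epochs on
#' class-balanced seeds.
#'
#' @param patch_size,stride Splitting geometry in pixels.
#' @param tau Segmentation threshold on attention/refined probabilities.
#' @param node_size Node block side length in pixels.
#' @param beta JSD edge threshold; `NULL` calibrates it per image from the
#'   pairwise-divergence distribution (see [calibrate_beta()]).
#' @param beta_quantile Quantile used when calibrating `beta`.
#' @param hidden GCN hidden widths (`c(64, 32)` = 3 layers).
#' @param epochs,lr GCN training controls; `epochs = 0` disables
#'   refinement.
#' @param label_high,label_low Pseudo-label seed thresholds on node
#'   probabilities (see [pseudo_labels()]).
#' @param class_balance Positive-class share of the GCN training loss.
#' @param consistency Neighbourhood-consistency seed filtering.
#' @param refine Whether to run GCN refinement at all.
#' @param double_positive_nodes Node-doubling ablation switch.
#' @param class Classifier column used as the class of interest (default:
#'   last column).
#' @param gt_min_pixels Ground-truth node membership minimum (evaluation).
#' @param hierarchy Optional [canopy_hierarchy()] for multi-tile images.
#' @param seed Base RNG seed for the refinement stage.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(patch_size = 64L, stride = 8L, tau = 0.5,
                       node_size = 8L, beta = 0.03, beta_quantile = 0.01,
                       hidden = c(64, 32),
                       epochs = 200L, lr = 0.01, label_high = 0.75,
                       label_low = 0.1, min_peak = 0.5, class_balance = 0.3,
                       consistency = TRUE,
                       refine = TRUE, double_positive_nodes = FALSE,
                       class = NULL, gt_min_pixels = 4L, hierarchy = NULL,
                       seed = 1L) {
  structure(as.list(environment()), class = "seg_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a config file with sections `split` (`patch_size`, `stride`),
#' `graph` (`beta`, `node_size`), `gcn` (`hidden`, `epochs`, `lr`,
#' `label_threshold`), `eval` (`tau`, `gt_min_pixels`), `hierarchy`
#' (passed to [canopy_hierarchy()]) and a top-level `seed`. Missing keys
#' keep their [seg_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `seg_config`.
#' @export
read_seg_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- seg_config()
  pick <- function(section, key, cur) {
    v <- y[[section]][[key]]
    if (is.null(v)) cur else v
  }
  cfg$patch_size <- as.integer(pick("split", "patch_size", cfg$patch_size))
  cfg$stride <- as.integer(pick("split", "stride", cfg$stride))
  cfg$beta <- pick("graph", "beta", cfg$beta)
  cfg$beta_quantile <- pick("graph", "beta_quantile", cfg$beta_quantile)
  cfg$node_size <- as.integer(pick("graph", "node_size", cfg$node_size))
  cfg$hidden <- unlist(pick("gcn", "hidden", cfg$hidden))
  cfg$epochs <- as.integer(pick("gcn", "epochs", cfg$epochs))
  cfg$lr <- pick("gcn", "lr", cfg$lr)
  cfg$label_high <- pick("gcn", "label_high", cfg$label_high)
  cfg$label_low <- pick("gcn", "label_low", cfg$label_low)
  cfg$min_peak <- pick("gcn", "min_peak", cfg$min_peak)
  cfg$class_balance <- pick("gcn", "class_balance", cfg$class_balance)
  cfg$tau <- pick("eval", "tau", cfg$tau)
  cfg$gt_min_pixels <- as.integer(pick("eval", "gt_min_pixels", cfg$gt_min_pixels))
  if (!is.null(y$hierarchy)) cfg$hierarchy <- do.call(canopy_hierarchy, y$hierarchy)
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  cfg
}

#' Canopy growing hierarchy
#'
#' The plant-factory layout: a table holds a grid of trays, each tray a
#' grid of cells (one plant per cell), and for processing each tray is
#' tiled into fixed-size input images. Defaults give a table of 3 x 3
#' trays, each tray 4 x 4 tiles of 352 x 576 px (16 input images per
#' tray) and 4 x 4 cells — a 4224 x 6912 px table that divides evenly
#' into tiles. All geometry is configurable; the tiling must be exact.
#'
#' @param table_rows,table_cols Table image size in pixels.
#' @param tile Tile size `c(rows, cols)` in pixels.
#' @param tray_tiles Tiles per tray, `c(rows, cols)`.
#' @param cells Cells per tray, `c(rows, cols)`.
#' @return An object of class `canopy_hierarchy`.
#' @export
canopy_hierarchy <- function(table_rows = 4224L, table_cols = 6912L,
                             tile = c(352L, 576L), tray_tiles = c(4L, 4L),
                             cells = c(4L, 4L)) {
  tray <- tile * tray_tiles
  if (table_rows %% tray[1] != 0L || table_cols %% tray[2] != 0L) {
    stop("invalid geometry: table does not divide into whole trays",
         call. = FALSE)
  }
  structure(list(table_rows = as.integer(table_rows),
                 table_cols = as.integer(table_cols),
                 tile = as.integer(tile), tray_tiles = as.integer(tray_tiles),
                 tray = as.integer(tray), cells = as.integer(cells),
                 trays = c(table_rows %/% tray[1], table_cols %/% tray[2])),
            class = "canopy_hierarchy")
}

# Tile offsets (top-left corners, 1-based) covering an image exactly.
tile_offsets <- function(M, N, tile) {
  if (M %% tile[1] != 0L || N %% tile[2] != 0L) {
    stop(sprintf("invalid geometry: %d x %d image does not divide into %d x %d tiles",
                 M, N, tile[1], tile[2]), call. = FALSE)
  }
  expand.grid(row = seq(1L, M, by = tile[1]), col = seq(1L, N, by = tile[2]))
}

#' Run the full weakly supervised segmentation pipeline
#'
#' Executes split -> classify -> attention map -> node re-split -> GCN
#' refinement -> reconstruction for an image (or each fixed-size tile of a
#' larger canopy image), merges tile masks back into source coordinates,
#' and attributes each detected region to its tray and cell. Only
#' image-level class knowledge enters through the classifier; no pixel
#' labels are used anywhere.
#'
#' @param image RGB array or path to an image file. Images larger than one
#'   tile must divide exactly into tiles
#'   (`config$hierarchy$tile`, default 352 x 576).
#' @param classifier A `patch_classifier` (trained model, stub or oracle).
#' @param config A [seg_config()].
#' @return An object of class `canopy_segmentation`: `mask` (integer
#'   matrix), `prob` (refined probability map at node resolution),
#'   `regions` (data frame of detected components with tray/cell ids,
#'   bounding boxes, areas and mean probabilities), `tiles`, and `config`.
#' @export
run_pipeline <- function(image, classifier, config = seg_config()) {
  if (is.character(image)) image <- read_image(image)
  image <- as_image_array(image)
  M <- dim(image)[1]; N <- dim(image)[2]
  tile <- if (!is.null(config$hierarchy)) config$hierarchy$tile
          else c(min(M, 352L), min(N, 576L))
  if (M == tile[1] && N == tile[2]) {
    offs <- data.frame(row = 1L, col = 1L)
  } else {
    offs <- tile_offsets(M, N, tile)
  }
  mask <- matrix(0L, M, N)
  prob <- matrix(0, M, N)
  tiles <- vector("list", nrow(offs))
  for (ti in seq_len(nrow(offs))) {
    r0 <- offs$row[ti]; c0 <- offs$col[ti]
    sub <- image[r0 + seq_len(tile[1]) - 1L, c0 + seq_len(tile[2]) - 1L, ,
                 drop = FALSE]
    res <- segment_tile(sub, classifier, config, seed_offset = ti)
    mask[r0 + seq_len(tile[1]) - 1L, c0 + seq_len(tile[2]) - 1L] <- res$mask
    prob[r0 + seq_len(tile[1]) - 1L, c0 + seq_len(tile[2]) - 1L] <- res$prob
    tiles[[ti]] <- list(row = r0, col = c0, positive_nodes = res$positive_nodes)
  }
  regions <- attribute_regions(mask, prob, config$hierarchy)
  structure(list(mask = mask, prob = prob, regions = regions, tiles = tiles,
                 config = config), class = "canopy_segmentation")
}

# One 352 x 576 (or config-sized) tile through the whole stack.
segment_tile <- function(tile_img, classifier, config, seed_offset = 0L) {
  M <- dim(tile_img)[1]; N <- dim(tile_img)[2]
  spec <- split_spec(M, N, config$patch_size, stride_rows = config$stride)
  co <- split_image(tile_img, spec)
  cop <- classify_configuration(co, classifier, class = config$class)
  ram <- build_ram(cop, spec)
  nodes <- resplit(tile_img, ram, config$node_size)
  if (isTRUE(config$refine) && config$epochs > 0L) {
    if (!is.null(config$seed)) set.seed(config$seed + seed_offset)
    hists <- node_histograms(nodes)
    beta <- config$beta
    if (is.null(beta)) beta <- calibrate_beta(hists, config$beta_quantile)
    graph <- build_adjacency(hists, beta)
    nodes <- withCallingHandlers(
      refine(nodes, classifier = classifier, graph = graph,
             label_high = config$label_high, label_low = config$label_low,
             min_peak = config$min_peak,
             class_balance = config$class_balance,
             consistency = config$consistency,
             hidden = config$hidden, epochs = config$epochs, lr = config$lr,
             seed = config$seed + seed_offset,
             double_positive_nodes = config$double_positive_nodes),
      warning = function(w) {
        if (grepl("degenerate pseudo-labeling", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  # node probabilities back to pixel resolution: constant over each block
  ns <- nodes$node_size
  prob <- nodes$cop[rep(seq_len(nodes$w), each = ns),
                    rep(seq_len(nodes$v), each = ns)]
  mask <- matrix(as.integer(prob >= config$tau), M, N)
  list(mask = mask, prob = prob,
       positive_nodes = predicted_node_set(nodes, config$tau))
}

#' Attribute mask components to trays and cells
#'
#' Labels the connected components of a segmentation mask and maps each to
#' the growing hierarchy: the tray containing its centroid and the cell
#' within that tray (components spanning cells are assigned by centroid).
#' Without a hierarchy the whole image is treated as one tray with one
#' cell.
#'
#' @param mask 0/1 or logical matrix in table coordinates.
#' @param prob Optional probability map for per-region mean probability.
#' @param hierarchy A [canopy_hierarchy()] or `NULL`.
#' @return Data frame with one row per component: `region`, `tray_row`,
#'   `tray_col`, `cell_row`, `cell_col`, bounding box (`r0, r1, c0, c1`),
#'   `area_px` and `mean_prob`.
#' @export
attribute_regions <- function(mask, prob = NULL, hierarchy = NULL) {
  lab <- EBImage::bwlabel(mask > 0)
  n <- max(lab)
  empty <- data.frame(region = integer(0), tray_row = integer(0),
                      tray_col = integer(0), cell_row = integer(0),
                      cell_col = integer(0), r0 = integer(0), r1 = integer(0),
                      c0 = integer(0), c1 = integer(0), area_px = integer(0),
                      mean_prob = numeric(0))
  if (n == 0L) return(empty)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    px <- which(lab == i, arr.ind = TRUE)
    cen <- colMeans(px)
    if (is.null(hierarchy)) {
      tray <- c(1L, 1L); cell <- c(1L, 1L)
    } else {
      tray <- pmin(ceiling(cen / hierarchy$tray), hierarchy$trays)
      within <- cen - (tray - 1L) * hierarchy$tray
      cell_px <- hierarchy$tray / hierarchy$cells
      cell <- pmin(ceiling(within / cell_px), hierarchy$cells)
    }
    out[[i]] <- data.frame(
      region = i, tray_row = as.integer(tray[1]), tray_col = as.integer(tray[2]),
      cell_row = as.integer(cell[1]), cell_col = as.integer(cell[2]),
      r0 = min(px[, 1]), r1 = max(px[, 1]),
      c0 = min(px[, 2]), c1 = max(px[, 2]),
      area_px = nrow(px),
      mean_prob = if (is.null(prob)) NA_real_ else mean(prob[px]))
  }
  do.call(rbind, out)
}

#' @export
print.canopy_segmentation <- function(x, ...) {
  cat(sprintf("canopy_segmentation: %d x %d, %d region(s), %.3f%% positive pixels\n",
              nrow(x$mask), ncol(x$mask), nrow(x$regions), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
summary.canopy_segmentation <- function(object, ...) {
  print(object)
  if (nrow(object$regions)) {
    cat("regions (tray, cell, bbox, area, mean prob):\n")
    print(object$regions, row.names = FALSE)
  } else {
    cat("no stress regions detected\n")
  }
  invisible(object)
}

#' @export
plot.canopy_segmentation <- function(x, what = c("mask", "prob"), ...) {
  what <- match.arg(what)
  m <- if (what == "mask") x$mask else x$prob
  graphics::image(t(m)[, rev(seq_len(nrow(m)))],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(m) / ncol(m), ...)
  invisible(x)
}

#' Write segmentation outputs to a directory
#'
#' Emits the binary mask as PNG, the probability map as 16-bit TIFF and
#' the region report as JSON (`{tray, cell, bbox [r0, r1, c0, c1], area_px,
#' mean_prob}` per region).
#'
#' @param x A `canopy_segmentation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_segmentation <- function(x, dir) {
  stopifnot(inherits(x, "canopy_segmentation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mask = file.path(dir, "mask.png"),
             prob = file.path(dir, "probability.tif"),
             report = file.path(dir, "regions.json"))
  write_image(x$mask, paths["mask"])
  tiff::writeTIFF(pmin(pmax(x$prob, 0), 1), paths["prob"],
                  bits.per.sample = 16L)
  jsonlite::write_json(x$regions, paths["report"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
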