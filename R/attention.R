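#' Reconstructed attention map
#'
#' Collapses a configuration of per-patch probabilities back onto the image
#' plane: every patch deposits its probability over its whole footprint,
#' the deposits are accumulated (`raw`), and dividing by the per-pixel
#' overlap count yields the averaged map (`averaged`), whose entries lie in
#' `[0, 1]` whenever the patch probabilities do. With a hard stride `s`
#' much smaller than the patch size the averaged map varies at the
#' resolution of `s x s` blocks — at stride 1 it is a per-pixel probability
#' map. Pixels covered by no patch (possible when strides do not tile the
#' image exactly) are flagged by overlap count 0 and hold value 0.
#'
#' @param cop `k1 x k2` matrix of patch probabilities
#'   (see [classify_configuration()]).
#' @param spec The [split_spec()] the probabilities were computed under.
#' @return An object of class `attention_map` with fields `raw`,
#'   `averaged`, `overlap` and `spec`.
#' @export
build_ram <- function(cop, spec) {
  if (!is.matrix(cop) || !all(dim(cop) == c(spec$k1, spec$k2))) {
    stop("invalid geometry: probability grid does not match spec", call. = FALSE)
  }
  raw <- collapse_to_image(cop, spec, reduce = "sum")
  overlap <- accumulate_overlap(spec)
  averaged <- raw / ifelse(overlap > 0L, overlap, 1L)
  structure(list(raw = raw, averaged = averaged, overlap = overlap,
                 spec = spec), class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cov <- mean(x$overlap > 0)
  cat(sprintf("attention_map: %d x %d, values in [%.3f, %.3f], %.1f%% covered\n",
              nrow(x$averaged), ncol(x$averaged),
              min(x$averaged), max(x$averaged), 100 * cov))
  invisible(x)
}

#' @export
plot.attention_map <- function(x, ...) {
  graphics::image(t(x$averaged)[, rev(seq_len(nrow(x$averaged)))],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(x$averaged) / ncol(x$averaged), ...)
  invisible(x)
}

#' Threshold an attention map into a binary mask
#'
#' The baseline segmentation: pixel `(x, y)` is positive when the averaged
#' attention value reaches `tau`. Uncovered pixels are always negative.
#'
#' @param ram An [build_ram()] attention map.
#' @param tau Probability threshold in `[0, 1]`.
#' @return `M x N` integer matrix of 0/1 values.
#' @export
threshold_ram <- function(ram, tau = 0.5) {
  stopifnot(inherits(ram, "attention_map"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1) {
    stop("tau must be a probability in [0, 1]", call. = FALSE)
  }
  mask <- (ram$averaged >= tau) & (ram$overlap > 0L)
  mask[] <- as.integer(mask)
  storage.mode(mask) <- "integer"
  mask
}

#' Re-split image and attention map into node blocks
#'
#' After overlap averaging the attention map carries information at the
#' stride resolution, so the image and the map are re-tiled into
#' non-overlapping `node_size x node_size` blocks ("nodes"). Each node
#' keeps its raw RGB block and one probability — the mean of its attention
#' block (exact when the map is uniform within the block, which holds for
#' stride-aligned geometries). For a 352 x 576 source with 8 px nodes this
#' yields a 44 x 72 grid of 3168 nodes, the per-image graph on which
#' pseudo-label refinement operates.
#'
#' Nodes are indexed column-major: node `(r, c)` of a `w`-row grid has
#' linear index `idx = w * (c - 1) + r`.
#'
#' @param x Source image `M x N x 3` with dims divisible by `node_size`.
#' @param ram The image's [build_ram()] attention map.
#' @param node_size Block side length in pixels.
#' @return An object of class `node_grid` with fields `blocks`
#'   (`node_size x node_size x 3 x w x v` array), `cop` (`w x v` matrix of
#'   node probabilities), `w`, `v`, `n` and `node_size`.
#' @export
resplit <- function(x, ram, node_size = 8L) {
  x <- as_image_array(x)
  stopifnot(inherits(ram, "attention_map"))
  M <- dim(x)[1]; N <- dim(x)[2]
  if (!all(dim(ram$averaged) == c(M, N))) {
    stop("invalid geometry: image and attention map dimensions differ",
         call. = FALSE)
  }
  if (M %% node_size != 0L || N %% node_size != 0L) {
    stop(sprintf("invalid geometry: %d x %d not divisible by node size %d",
                 M, N, node_size), call. = FALSE)
  }
  node_size <- as.integer(node_size)
  w <- as.integer(M %/% node_size); v <- as.integer(N %/% node_size)
  blocks <- aperm(array(x, c(node_size, w, node_size, v, dim(x)[3])),
                  c(1L, 3L, 5L, 2L, 4L))
  m <- array(ram$averaged, c(node_size, w, node_size, v))
  # mean over the two in-block axes
  cop <- apply(m, c(2L, 4L), mean)
  structure(list(blocks = blocks, cop = cop, w = w, v = v,
                 n = w * v, node_size = node_size),
            class = "node_grid")
}

#' @export
print.node_grid <- function(x, ...) {
  cat(sprintf("node_grid: %d x %d nodes (%d) of %d x %d px, probabilities in [%.3f, %.3f]\n",
              x$w, x$v, x$n, x$node_size, x$node_size, min(x$cop), max(x$cop)))
  invisible(x)
}

#' Linear node index of a grid cell
#'
#' Column-major indexing `idx = w * (c - 1) + r` relating grid coordinates
#' to rows of the node feature matrix.
#'
#' @param r,c Node grid coordinates, 1-based.
#' @param w Number of grid rows.
#' @return Integer linear index.
#' @export
node_index <- function(r, c, w) {
  as.integer(w * (c - 1L) + r)
}
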