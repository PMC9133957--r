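#' Tiling geometry for hard-stride patch splitting
#'
#' A `split_spec` records how an `M x N x d` image is cut into a `k1 x k2`
#' grid of `p_x x p_y x d` patches with strides `(s_x, s_y)`. No padding is
#' used: every patch lies fully inside the image, so the grid counts are
#' `k = floor((dim - patch) / stride) + 1` per axis. With a *hard* stride
#' (stride much smaller than the patch) neighbouring patches overlap
#' heavily; that overlap is what turns per-patch class probabilities into a
#' pixel-resolution attention map.
#'
#' Coordinates are 1-based and row/column ordered as in base R: patch
#' `(r, c)` covers source rows `(r-1)*s_x + 1:p_x` and columns
#' `(c-1)*s_y + 1:p_y`. When the strides do not tile the image exactly, a
#' trailing band of pixels is covered by no patch; such pixels carry
#' overlap count 0 and are excluded from reconstructed maps.
#'
#' @param image_rows,image_cols Image size in pixels.
#' @param patch_rows,patch_cols Patch size in pixels; `patch_cols` defaults
#'   to `patch_rows`.
#' @param stride_rows,stride_cols Stride in pixels; default is the patch
#'   size (non-overlapping tiling).
#' @param channels Number of image channels.
#' @return An object of class `split_spec` with the grid counts `k1`, `k2`
#'   derived.
#' @examples
#' sp <- split_spec(160, 195, 64, stride_rows = 8)
#' sp$k1  # 13
#' sp$k2  # 17
#' @export
split_spec <- function(image_rows, image_cols,
                       patch_rows, patch_cols = patch_rows,
                       stride_rows = patch_rows, stride_cols = stride_rows,
                       channels = 3L) {
  spec <- list(
    M = as.integer(image_rows), N = as.integer(image_cols),
    d = as.integer(channels),
    p_x = as.integer(patch_rows), p_y = as.integer(patch_cols),
    s_x = as.integer(stride_rows), s_y = as.integer(stride_cols)
  )
  spec$k1 <- compute_grid(spec$M, spec$p_x, spec$s_x)
  spec$k2 <- compute_grid(spec$N, spec$p_y, spec$s_y)
  structure(spec, class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec: %d x %d x %d image, %d x %d patches, stride (%d, %d) -> %d x %d grid (%d patches)\n",
              x$M, x$N, x$d, x$p_x, x$p_y, x$s_x, x$s_y, x$k1, x$k2, x$k1 * x$k2))
  invisible(x)
}

#' Number of stride positions along one axis
#'
#' Counts the patches that fit fully inside one image dimension, i.e.
#' `floor((dim - patch) / stride) + 1`. This is the no-padding convolution
#' output size; equivalently the cardinality of the start-offset set
#' `{0, s, 2s, ...}` intersected with `{o : o + patch <= dim}`.
#'
#' @param dim Image extent in pixels.
#' @param patch Patch extent in pixels; must satisfy `1 <= patch <= dim`.
#' @param stride Stride in pixels; must be `>= 1`.
#' @return Integer patch count.
#' @examples
#' compute_grid(160, 64, 8)  # 13
#' compute_grid(195, 64, 8)  # 17
#' @export
compute_grid <- function(dim, patch, stride) {
  dim <- as.integer(dim); patch <- as.integer(patch); stride <- as.integer(stride)
  if (length(dim) != 1L || length(patch) != 1L || length(stride) != 1L ||
      is.na(dim) || is.na(patch) || is.na(stride)) {
    stop("compute_grid() expects scalar integer arguments", call. = FALSE)
  }
  if (patch < 1L || patch > dim) {
    stop(sprintf("invalid geometry: patch size %d outside [1, %d]", patch, dim),
         call. = FALSE)
  }
  if (stride < 1L) stop("invalid geometry: stride must be >= 1", call. = FALSE)
  (dim - patch) %/% stride + 1L
}

as_image_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("expected an M x N or M x N x d image array", call. = FALSE)
  }
  x
}

check_spec_dims <- function(x, spec) {
  d <- dim(x)
  if (d[1] != spec$M || d[2] != spec$N || d[3] != spec$d) {
    stop(sprintf("invalid geometry: image is %d x %d x %d but spec expects %d x %d x %d",
                 d[1], d[2], d[3], spec$M, spec$N, spec$d), call. = FALSE)
  }
  invisible(TRUE)
}

#' Split an image into an overlapping patch configuration
#'
#' Extracts the `k1 x k2` grid of patches described by a [split_spec()].
#' Patch `(r, c)` is a copy of the source block starting at pixel
#' `((r-1)*s_x + 1, (c-1)*s_y + 1)`.
#'
#' @param x Image array `M x N x d` (a matrix is treated as `d = 1`).
#' @param spec A [split_spec()] matching the image dimensions.
#' @return A `patch_config`: list with `spec` and `patches`, a `k1 x k2`
#'   list-matrix of `p_x x p_y x d` arrays.
#' @export
split_image <- function(x, spec) {
  x <- as_image_array(x)
  check_spec_dims(x, spec)
  patches <- vector("list", spec$k1 * spec$k2)
  dim(patches) <- c(spec$k1, spec$k2)
  for (c_ in seq_len(spec$k2)) {
    cols <- (c_ - 1L) * spec$s_y + seq_len(spec$p_y)
    for (r_ in seq_len(spec$k1)) {
      rows <- (r_ - 1L) * spec$s_x + seq_len(spec$p_x)
      patches[[r_, c_]] <- x[rows, cols, , drop = FALSE]
    }
  }
  structure(list(spec = spec, patches = patches), class = "patch_config")
}

#' @export
print.patch_config <- function(x, ...) {
  cat(sprintf("patch_config: %d x %d grid of %d x %d x %d patches\n",
              x$spec$k1, x$spec$k2, x$spec$p_x, x$spec$p_y, x$spec$d))
  invisible(x)
}

#' Map a patch-local pixel to source-image coordinates
#'
#' Pixel `(i, j)` of patch `(r, c)` lands on source pixel
#' `(i + (r-1)*s_x, j + (c-1)*s_y)`. This mapping both places patch values
#' back on the image plane during reconstruction and defines the overlap
#' counts.
#'
#' @param r,c Patch grid indices, 1-based.
#' @param i,j Pixel indices within the patch, 1-based.
#' @param spec A [split_spec()].
#' @return Integer vector `c(x, y)` of source coordinates.
#' @export
patch_to_pixel <- function(r, c, i, j, spec) {
  if (any(r < 1L) || any(r > spec$k1) || any(c < 1L) || any(c > spec$k2)) {
    stop("patch index out of range", call. = FALSE)
  }
  if (any(i < 1L) || any(i > spec$p_x) || any(j < 1L) || any(j > spec$p_y)) {
    stop("in-patch pixel index out of range", call. = FALSE)
  }
  c(x = as.integer(i + (r - 1L) * spec$s_x),
    y = as.integer(j + (c - 1L) * spec$s_y))
}

#' Per-pixel patch overlap counts
#'
#' Entry `(x, y)` counts how many patches of the configuration cover source
#' pixel `(x, y)`. Coverage is separable across axes, so the matrix is the
#' outer product of per-axis coverage counts; the total over all entries is
#' `k1 * k2 * p_x * p_y` (each patch contributes its full area).
#'
#' @param spec A [split_spec()].
#' @return `M x N` integer matrix of counts (0 on pixels no patch reaches).
#' @export
accumulate_overlap <- function(spec) {
  axis_cover <- function(dim, patch, stride, k) {
    cnt <- integer(dim)
    for (r in seq_len(k)) {
      idx <- (r - 1L) * stride + seq_len(patch)
      cnt[idx] <- cnt[idx] + 1L
    }
    cnt
  }
  rowc <- axis_cover(spec$M, spec$p_x, spec$s_x, spec$k1)
  colc <- axis_cover(spec$N, spec$p_y, spec$s_y, spec$k2)
  out <- outer(rowc, colc)
  storage.mode(out) <- "integer"
  out
}

#' Collapse patch-space data back to the image plane
#'
#' The inverse of [split_image()]: every patch pixel is added at its mapped
#' source location. `values` may be a `k1 x k2` list-matrix of per-patch
#' arrays (as produced by [split_image()]), or a plain `k1 x k2` numeric
#' matrix, in which case each entry is treated as a constant patch — the
#' form a configuration of per-patch probabilities takes.
#'
#' With `reduce = "average"` the accumulated sum is divided entrywise by
#' the overlap counts; pixels covered by no patch stay 0. Averaging the
#' collapse of [split_image()] output reproduces the source exactly on the
#' covered region, because all overlapping copies agree.
#'
#' @param values Patch-shaped data (see Details).
#' @param spec A [split_spec()].
#' @param reduce `"average"` (default) or `"sum"`.
#' @return An `M x N` matrix or `M x N x d'` array in source coordinates.
#' @export
collapse_to_image <- function(values, spec, reduce = c("average", "sum")) {
  reduce <- match.arg(reduce)
  scalar <- is.numeric(values) && is.matrix(values)
  if (scalar) {
    if (!all(dim(values) == c(spec$k1, spec$k2))) {
      stop("invalid geometry: values grid does not match spec", call. = FALSE)
    }
    dprime <- 1L
  } else {
    if (inherits(values, "patch_config")) values <- values$patches
    if (!is.list(values) || !all(dim(values) == c(spec$k1, spec$k2))) {
      stop("invalid geometry: values grid does not match spec", call. = FALSE)
    }
    first <- as_image_array(values[[1L, 1L]])
    if (dim(first)[1] != spec$p_x || dim(first)[2] != spec$p_y) {
      stop("invalid geometry: patch entries do not match spec patch size",
           call. = FALSE)
    }
    dprime <- dim(first)[3]
  }
  acc <- array(0, c(spec$M, spec$N, dprime))
  for (c_ in seq_len(spec$k2)) {
    cols <- (c_ - 1L) * spec$s_y + seq_len(spec$p_y)
    for (r_ in seq_len(spec$k1)) {
      rows <- (r_ - 1L) * spec$s_x + seq_len(spec$p_x)
      if (scalar) {
        acc[rows, cols, 1L] <- acc[rows, cols, 1L] + values[r_, c_]
      } else {
        acc[rows, cols, ] <- acc[rows, cols, ] + as.vector(values[[r_, c_]])
      }
    }
  }
  if (reduce == "average") {
    ov <- accumulate_overlap(spec)
    div <- ifelse(ov > 0L, ov, 1L)
    acc <- sweep(acc, c(1L, 2L), div, "/")
  }
  if (dprime == 1L) acc[, , 1L] else acc
}
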