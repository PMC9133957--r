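#' Area-averaged image resize
#'
#' Resamples an image to a new size by exact area-weighted averaging: each
#' output pixel is the mean of the source region it covers, with partial
#' source pixels weighted by their overlap fraction. For integer
#' downscaling factors this reduces to block averaging, which makes it a
#' properly antialiased scaling transform for feeding patches of arbitrary
#' size to a fixed-input classifier; for upscaling it behaves like
#' first-order interpolation.
#'
#' @param x Image (`M x N` matrix or `M x N x d` array), values any range.
#' @param out_rows,out_cols Target size in pixels.
#' @return Resized matrix/array of the same channel count.
#' @export
resize_area <- function(x, out_rows, out_cols) {
  was_matrix <- is.matrix(x)
  x <- as_image_array(x)
  wr <- area_weights(dim(x)[1], out_rows)
  wc <- area_weights(dim(x)[2], out_cols)
  out <- array(0, c(out_rows, out_cols, dim(x)[3]))
  for (ch in seq_len(dim(x)[3])) {
    out[, , ch] <- wr %*% x[, , ch] %*% t(wc)
  }
  if (was_matrix) out[, , 1L] else out
}

# Row-stochastic n_out x n_in matrix of interval-overlap weights.
area_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    a <- (i - 1) * scale
    b <- i * scale
    j0 <- floor(a) + 1L
    j1 <- min(ceiling(b), n_in)
    for (j in j0:j1) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) w[i, j] <- ov / scale
    }
  }
  w
}

# Reflect 1-based indices into [1, n] (boundary-repeating reflection).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  m <- (idx - 1L) %% period
  m <- ifelse(m < 0L, m + period, m)
  as.integer(ifelse(m < n, m + 1L, period - m))
}

#' Gaussian blur with reflected borders
#'
#' Separable Gaussian filtering with kernel half-width `ceiling(3*sigma)`;
#' borders are handled by reflection so image statistics are preserved at
#' the edges.
#'
#' @param x Image matrix or array.
#' @param sigma Standard deviation in pixels.
#' @return Blurred image of the same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  was_matrix <- is.matrix(x)
  x <- as_image_array(x)
  h <- as.integer(ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  M <- dim(x)[1]; N <- dim(x)[2]
  out <- x
  for (ch in seq_len(dim(x)[3])) {
    plane <- x[, , ch]
    tmp <- matrix(0, M, N)
    for (o in -h:h) {
      tmp <- tmp + k[o + h + 1L] * plane[reflect_index(seq_len(M) + o, M), , drop = FALSE]
    }
    res <- matrix(0, M, N)
    for (o in -h:h) {
      res <- res + k[o + h + 1L] * tmp[, reflect_index(seq_len(N) + o, N), drop = FALSE]
    }
    out[, , ch] <- res
  }
  if (was_matrix) out[, , 1L] else out
}

#' Rotate an image about its centre
#'
#' Bilinear resampling of the inverse-mapped rotation; pixels whose
#' pre-image falls outside the source are filled by border reflection, so
#' rotated texture patches stay texture-like in the exposed corners.
#'
#' @param x Image matrix or array.
#' @param angle Rotation angle in degrees (counter-clockwise).
#' @return Rotated image, same shape as the input.
#' @export
rotate_image <- function(x, angle) {
  was_matrix <- is.matrix(x)
  x <- as_image_array(x)
  M <- dim(x)[1]; N <- dim(x)[2]
  th <- angle * pi / 180
  cx <- (M + 1) / 2; cy <- (N + 1) / 2
  gr <- matrix(seq_len(M), M, N) - cx
  gc <- matrix(seq_len(N), M, N, byrow = TRUE) - cy
  # inverse rotation of output coordinates into the source plane
  sr <- cos(th) * gr + sin(th) * gc + cx
  sc <- -sin(th) * gr + cos(th) * gc + cy
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  i00 <- cbind(reflect_index(r0, M), reflect_index(c0, N))
  i01 <- cbind(reflect_index(r0, M), reflect_index(c0 + 1, N))
  i10 <- cbind(reflect_index(r0 + 1, M), reflect_index(c0, N))
  i11 <- cbind(reflect_index(r0 + 1, M), reflect_index(c0 + 1, N))
  out <- x
  for (ch in seq_len(dim(x)[3])) {
    plane <- x[, , ch]
    out[, , ch] <- matrix(
      plane[i00] * (1 - fr) * (1 - fc) + plane[i01] * (1 - fr) * fc +
        plane[i10] * fr * (1 - fc) + plane[i11] * fr * fc,
      M, N)
  }
  if (was_matrix) out[, , 1L] else out
}

#' Flip an image vertically or horizontally
#'
#' `flip_ud()` reverses rows (up-down), `flip_lr()` reverses columns
#' (left-right). Both are involutions.
#'
#' @param x Image matrix or array.
#' @return Flipped image.
#' @export
flip_ud <- function(x) {
  if (is.matrix(x)) x[rev(seq_len(nrow(x))), , drop = FALSE]
  else x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
}

#' @rdname flip_ud
#' @export
flip_lr <- function(x) {
  if (is.matrix(x)) x[, rev(seq_len(ncol(x))), drop = FALSE]
  else x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
}

#' Median-cut colour quantization
#'
#' Reduces an RGB image to at most `n_colors` distinct colours by the
#' median-cut algorithm: colour boxes are split recursively along their
#' widest channel at the median until the palette size is reached, then
#' every pixel is replaced by its box mean.
#'
#' @param x RGB image array with values in `[0, 1]`.
#' @param n_colors Palette size, at least 2.
#' @return Quantized image of the same shape.
#' @export
quantize_colors <- function(x, n_colors = 8L) {
  if (n_colors < 2L) stop("n_colors must be >= 2", call. = FALSE)
  x <- as_image_array(x)
  px <- matrix(x, ncol = dim(x)[3])
  boxes <- list(seq_len(nrow(px)))
  while (length(boxes) < n_colors) {
    ranges <- vapply(boxes, function(b) {
      if (length(b) < 2L) return(-1)
      max(apply(px[b, , drop = FALSE], 2, function(v) diff(range(v))))
    }, numeric(1))
    pick <- which.max(ranges)
    if (ranges[pick] <= 0) break
    b <- boxes[[pick]]
    sub <- px[b, , drop = FALSE]
    chan <- which.max(apply(sub, 2, function(v) diff(range(v))))
    ord <- order(sub[, chan])
    half <- length(b) %/% 2L
    boxes[[pick]] <- b[ord[seq_len(half)]]
    boxes[[length(boxes) + 1L]] <- b[ord[(half + 1L):length(b)]]
  }
  out <- px
  for (b in boxes) {
    out[b, ] <- matrix(colMeans(px[b, , drop = FALSE]),
                       length(b), ncol(px), byrow = TRUE)
  }
  array(out, dim(x))
}
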