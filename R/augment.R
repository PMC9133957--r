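#' Augmentation policy for training patches
#'
#' Describes the stochastic transforms applied to 64 x 64 x 3 training
#' patches: random rotation in `[0, 90]` degrees (reflection fill), up-down
#' and left-right flips, median-cut colour quantization to 8 colours,
#' zoom-in (scale then centre-crop), zoom-out (edge padding then rescale)
#' and Gaussian blurring with random sigma in `(0.5, 2)` pixels. Each
#' transform fires independently with probability `apply_prob`; the sampled
#' parameters stay within the stated ranges.
#'
#' @param rotation Angle range in degrees.
#' @param flip_ud,flip_lr Enable the two flips.
#' @param n_colors Quantization palette size (>= 2).
#' @param zoom_in Scale range for zoom-in (>= 1).
#' @param zoom_out Padding range in pixels per side for zoom-out.
#' @param blur_sigma Gaussian sigma range in pixels, within `(0.5, 2)`.
#' @param apply_prob Per-transform firing probability.
#' @param seed Optional seed fixing the whole augmentation stream.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(rotation = c(0, 90), flip_ud = TRUE, flip_lr = TRUE,
                           n_colors = 8L, zoom_in = c(1, 1.5),
                           zoom_out = c(0, 8), blur_sigma = c(0.5, 2),
                           apply_prob = 0.5, seed = NULL) {
  if (n_colors < 2L) stop("n_colors must be >= 2", call. = FALSE)
  if (blur_sigma[1] < 0.5 || blur_sigma[2] > 2) {
    stop("blur_sigma range must lie within (0.5, 2)", call. = FALSE)
  }
  structure(list(rotation = rotation, flip_ud = flip_ud, flip_lr = flip_lr,
                 n_colors = as.integer(n_colors), zoom_in = zoom_in,
                 zoom_out = zoom_out, blur_sigma = blur_sigma,
                 apply_prob = apply_prob, seed = seed),
            class = "augment_policy")
}

#' Apply a random augmentation to one patch
#'
#' Samples transform parameters from the policy and applies the selected
#' transforms in a fixed order (rotate, flips, quantize, zoom, blur). The
#' output always has the spatial dimensions and channel count of the
#' input; the parameters actually used are attached as attribute
#' `"params"`. With `policy$seed` set (or the caller seeding the RNG) the
#' result is deterministic.
#'
#' @param patch RGB array in `[0, 1]`.
#' @param policy An [augment_policy()].
#' @return Augmented patch of identical shape.
#' @export
augment <- function(patch, policy = augment_policy()) {
  stopifnot(inherits(policy, "augment_policy"))
  if (!is.null(policy$seed)) set.seed(policy$seed)
  patch <- as_image_array(patch)
  M <- dim(patch)[1]; N <- dim(patch)[2]
  fire <- function() stats::runif(1) < policy$apply_prob
  params <- list()
  if (fire()) {
    params$angle <- stats::runif(1, policy$rotation[1], policy$rotation[2])
    patch <- rotate_image(patch, params$angle)
  }
  if (policy$flip_ud && fire()) {
    params$flip_ud <- TRUE
    patch <- flip_ud(patch)
  }
  if (policy$flip_lr && fire()) {
    params$flip_lr <- TRUE
    patch <- flip_lr(patch)
  }
  if (fire()) {
    params$n_colors <- policy$n_colors
    patch <- quantize_colors(patch, policy$n_colors)
  }
  if (fire()) {
    if (stats::runif(1) < 0.5) {
      params$zoom_in <- stats::runif(1, policy$zoom_in[1], policy$zoom_in[2])
      big <- resize_area(patch, max(M, round(M * params$zoom_in)),
                         max(N, round(N * params$zoom_in)))
      r0 <- (dim(big)[1] - M) %/% 2L
      c0 <- (dim(big)[2] - N) %/% 2L
      patch <- big[r0 + seq_len(M), c0 + seq_len(N), , drop = FALSE]
    } else {
      pad <- round(stats::runif(1, policy$zoom_out[1], policy$zoom_out[2]))
      params$zoom_out <- pad
      if (pad > 0) {
        ridx <- reflect_index(seq_len(M + 2L * pad) - pad, M)
        cidx <- reflect_index(seq_len(N + 2L * pad) - pad, N)
        patch <- resize_area(patch[ridx, cidx, , drop = FALSE], M, N)
      }
    }
  }
  if (fire()) {
    params$sigma <- stats::runif(1, policy$blur_sigma[1], policy$blur_sigma[2])
    patch <- gaussian_blur(patch, params$sigma)
  }
  patch <- pmin(pmax(patch, 0), 1)
  attr(patch, "params") <- params
  patch
}
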