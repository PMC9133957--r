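#' Sample foreground/background training patches from a leaf image
#'
#' Single-leaf datasets arrange one leaf on a near-uniform background, so
#' labels come for free: the four 8 x 8 x 3 corner patches are background,
#' and six 8 x 8 x 3 patches drawn from the image centre are foreground.
#' Centre positions are sampled uniformly from the central third of the
#' image; with the RNG seeded the positions are reproducible.
#'
#' @param image RGB array, at least 24 x 24.
#' @param patch_size Patch side length in pixels.
#' @param n_center Number of centre (foreground) patches.
#' @return List with `patches` (list of arrays), `labels` (factor
#'   background/foreground) and `positions` (top-left corners).
#' @export
sample_training_patches <- function(image, patch_size = 8L, n_center = 6L) {
  image <- as_image_array(image)
  M <- dim(image)[1]; N <- dim(image)[2]
  if (M < 3L * patch_size || N < 3L * patch_size) {
    stop("image too small to sample corner and centre patches", call. = FALSE)
  }
  corners <- rbind(c(1L, 1L), c(1L, N - patch_size + 1L),
                   c(M - patch_size + 1L, 1L),
                   c(M - patch_size + 1L, N - patch_size + 1L))
  lo_r <- floor(M / 3); hi_r <- floor(2 * M / 3) - patch_size + 1L
  lo_c <- floor(N / 3); hi_c <- floor(2 * N / 3) - patch_size + 1L
  centers <- cbind(
    sample(seq(lo_r, max(lo_r, hi_r)), n_center, replace = TRUE),
    sample(seq(lo_c, max(lo_c, hi_c)), n_center, replace = TRUE))
  pos <- rbind(corners, centers)
  patches <- lapply(seq_len(nrow(pos)), function(i) {
    image[pos[i, 1] + seq_len(patch_size) - 1L,
          pos[i, 2] + seq_len(patch_size) - 1L, , drop = FALSE]
  })
  list(patches = patches,
       labels = factor(rep(c("background", "foreground"), c(4L, n_center)),
                       levels = c("background", "foreground")),
       positions = pos)
}

#' Train the foreground/background separator
#'
#' A small multilayer perceptron over flattened `8 x 8 x 3` patches
#' (192 inputs, hidden layers 64 and 32) trained on the automatically
#' sampled corner/centre patches pooled across a set of images.
#'
#' @param images List of RGB arrays (or a single array).
#' @param patch_size Patch side length.
#' @param hidden Hidden-layer widths.
#' @param epochs,seed,... Passed to the internal optimiser.
#' @return An object of class `foreground_model`.
#' @export
train_foreground_model <- function(images, patch_size = 8L, hidden = c(64, 32),
                                   epochs = 80, seed = NULL, ...) {
  if (is.array(images)) images <- list(images)
  if (!is.null(seed)) set.seed(seed)
  samp <- lapply(images, sample_training_patches, patch_size = patch_size)
  X <- do.call(rbind, lapply(samp, function(s) {
    t(vapply(s$patches, as.vector, numeric(3L * patch_size^2)))
  }))
  y <- factor(unlist(lapply(samp, function(s) as.character(s$labels))),
              levels = c("background", "foreground"))
  model <- fit_mlp(X, y, hidden = hidden, epochs = epochs, lr = 0.01,
                   batch_size = 16, ...)
  structure(list(model = model, patch_size = as.integer(patch_size)),
            class = "foreground_model")
}

#' @export
print.foreground_model <- function(x, ...) {
  cat(sprintf("foreground_model: %d x %d windows, MLP %s\n",
              x$patch_size, x$patch_size,
              paste(vapply(x$model$layers, function(l) ncol(l$W), integer(1)),
                    collapse = " -> ")))
  invisible(x)
}

#' Per-pixel foreground probability of a leaf image
#'
#' Slides the separator over every pixel (window centred, borders
#' reflected) and returns the foreground probability map.
#'
#' @param image RGB array.
#' @param model A [train_foreground_model()] fit.
#' @return Matrix of probabilities in `[0, 1]`.
#' @export
foreground_probability <- function(image, model) {
  image <- as_image_array(image)
  M <- dim(image)[1]; N <- dim(image)[2]
  ps <- model$patch_size
  off <- seq_len(ps) - 1L - (ps %/% 2L)
  # im2col: one shifted copy of the image per in-window offset/channel
  X <- matrix(0, M * N, 3L * ps * ps)
  k <- 0L
  for (ch in 1:3) {
    plane <- image[, , ch]
    for (oc in off) {
      cidx <- reflect_index(seq_len(N) + oc, N)
      for (or in off) {
        k <- k + 1L
        X[, k] <- as.vector(plane[reflect_index(seq_len(M) + or, M), cidx])
      }
    }
  }
  P <- predict_mlp(model$model, X)
  matrix(P[, "foreground"], M, N)
}

#' Remove the background of a single-leaf image
#'
#' Classifies every pixel with the foreground separator, keeps the largest
#' connected foreground component (speckles would otherwise distort the
#' crop), zeroes background pixels to exactly `(0, 0, 0)` so they cannot
#' influence downstream classification, crops to the foreground bounding
#' box and rescales to the dataset's target size.
#'
#' @param image RGB array.
#' @param model A [train_foreground_model()] fit.
#' @param out_size Target `c(rows, cols)` after cropping; `NULL` keeps the
#'   cropped size.
#' @param threshold Foreground decision threshold.
#' @return List with `image` (masked, cropped, resized), `mask` (logical,
#'   source coordinates) and `bbox` (`r0, r1, c0, c1`).
#' @export
remove_background <- function(image, model, out_size = c(256L, 256L),
                              threshold = 0.5) {
  image <- as_image_array(image)
  prob <- foreground_probability(image, model)
  mask <- prob >= threshold
  if (!any(mask)) {
    warning("empty foreground: returning the image uncropped")
    return(list(image = image, mask = mask,
                bbox = c(1L, nrow(mask), 1L, ncol(mask))))
  }
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[!mask] <- 0
    out[, , ch] <- plane
  }
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  out <- out[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
  if (!is.null(out_size)) out <- resize_area(out, out_size[1], out_size[2])
  list(image = out, mask = mask, bbox = c(rr[1], rr[2], cc[1], cc[2]))
}

#' Clean a class-folder leaf dataset
#'
#' Applies [remove_background()] to every image of a
#' one-directory-per-class dataset, writing the cleaned images to a
#' mirrored folder tree. The separator is trained once on patches pooled
#' across the whole dataset.
#'
#' @param in_dir Dataset root (class subdirectories of images).
#' @param out_dir Output root, mirrored layout.
#' @param out_size Target size per image (e.g. `c(264, 400)` for
#'   long-format leaf datasets, `c(256, 256)` otherwise).
#' @param seed RNG seed for patch sampling and training.
#' @return Invisibly, the paths written.
#' @export
clean_leaf_dataset <- function(in_dir, out_dir, out_size = c(256L, 256L),
                               seed = NULL) {
  ds <- read_patch_dir(in_dir)
  model <- train_foreground_model(ds$patches, seed = seed)
  classes <- list.dirs(in_dir, recursive = FALSE)
  written <- character(0)
  for (cl in classes) {
    files <- list.files(cl, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        full.names = TRUE, ignore.case = TRUE)
    dir.create(file.path(out_dir, basename(cl)), recursive = TRUE,
               showWarnings = FALSE)
    for (f in files) {
      res <- remove_background(read_image(f), model, out_size = out_size)
      dest <- file.path(out_dir, basename(cl),
                        paste0(tools::file_path_sans_ext(basename(f)), ".png"))
      write_image(res$image, dest)
      written <- c(written, dest)
    }
  }
  invisible(written)
}
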