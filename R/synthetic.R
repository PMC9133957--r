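# Deterministic synthetic canopies and single-leaf images with exact
# ground-truth masks. The canopy generator emulates the statistical
# structure the segmentation method relies on: a dense green texture of
# overlapping leaf blobs that looks canopy-like at every crop scale (the
# decomposition principle), with rare, small, sparse yellow-brown lesions.

hsv_px <- function(h, s, v) {
  # vectorized HSV -> RGB, all components in [0, 1]
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# logical mask of an ellipse over the index window rows x cols
ellipse_mask <- function(rows, cols, cr, cc, a, b, theta) {
  dr <- matrix(rows, length(rows), length(cols)) - cr
  dc <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cc
  u <- (cos(theta) * dr + sin(theta) * dc) / a
  w <- (-sin(theta) * dr + cos(theta) * dc) / b
  u^2 + w^2 <= 1
}

paint_ellipse <- function(img, cr, cc, a, b, theta, rgb) {
  M <- dim(img)[1]; N <- dim(img)[2]
  rows <- max(1L, floor(cr - max(a, b))):min(M, ceiling(cr + max(a, b)))
  cols <- max(1L, floor(cc - max(a, b))):min(N, ceiling(cc + max(a, b)))
  m <- ellipse_mask(rows, cols, cr, cc, a, b, theta)
  for (ch in 1:3) {
    plane <- img[rows, cols, ch]
    plane[m] <- rgb[ch]
    img[rows, cols, ch] <- plane
  }
  img
}

#' Synthetic canopy specification
#'
#' Parameters of the generated canopy: a dense texture of randomized green
#' "leaf" ellipses with a smooth brightness field and pixel noise, plus a
#' sparse Poisson number of small yellow-brown lesions of known extent.
#' Defaults mirror the operating conditions of the canopy pipeline: a
#' 352 x 576 px tile, a handful (mean 3) of lesions of 4-12 px — lesions
#' are rare, small and easily hidden in the texture.
#'
#' @param rows,cols Image size in pixels.
#' @param leaf_px Average pixels per background leaf blob (texture
#'   density).
#' @param leaf_size Semi-axis range of the leaf blobs in pixels; at the
#'   canopy imaging scale (a few plants per tile) individual leaves span
#'   tens of pixels with smooth interiors.
#' @param green_hue,green_sat,green_val HSV ranges of the leaf texture.
#' @param brightness Range of the smooth multiplicative brightness field.
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param lesion_mean Poisson mean of the lesion count.
#' @param lesion_size Lesion diameter range in pixels.
#' @param lesion_hue,lesion_sat,lesion_val HSV ranges of lesion colour
#'   (yellow-brown, well separated in hue from the green texture).
#' @param margin Minimum lesion distance from the tile border in pixels.
#'   The default keeps lesions inside the fully-overlapped interior (at
#'   least one patch width from the border): within a patch width of the
#'   edge the overlap-averaged attention map has systematically fewer
#'   covering windows and hence coarser spatial selectivity.
#' @param seed RNG seed; same seed, same canopy.
#' @return An object of class `canopy_spec`.
#' @export
canopy_spec <- function(rows = 352L, cols = 576L, leaf_px = 1500,
                        leaf_size = c(24, 56),
                        green_hue = c(0.27, 0.33), green_sat = c(0.55, 0.75),
                        green_val = c(0.40, 0.60), brightness = c(0.97, 1.03),
                        noise_sd = 0.005, lesion_mean = 3,
                        lesion_size = c(4, 12), lesion_hue = c(0.07, 0.13),
                        lesion_sat = c(0.65, 0.95), lesion_val = c(0.55, 0.85),
                        margin = 72L, seed = NULL) {
  structure(as.list(environment()), class = "canopy_spec")
}

render_canopy_texture <- function(rows, cols, spec) {
  base <- hsv_px(mean(spec$green_hue), 0.8, 0.30)
  img <- array(rep(base, each = rows * cols), c(rows, cols, 3L))
  n_leaves <- ceiling(rows * cols / spec$leaf_px)
  for (i in seq_len(n_leaves)) {
    a <- stats::runif(1, spec$leaf_size[1], spec$leaf_size[2])
    b <- stats::runif(1, 0.5, 1) * a
    col <- hsv_px(stats::runif(1, spec$green_hue[1], spec$green_hue[2]),
                  stats::runif(1, spec$green_sat[1], spec$green_sat[2]),
                  stats::runif(1, spec$green_val[1], spec$green_val[2]))
    img <- paint_ellipse(img, stats::runif(1, 1, rows),
                         stats::runif(1, 1, cols), a, b,
                         stats::runif(1, 0, pi), col)
  }
  # smooth brightness field: coarse random grid upsampled over the image
  gr <- max(2L, ceiling(rows / 48)); gc <- max(2L, ceiling(cols / 48))
  field <- resize_area(matrix(stats::runif(gr * gc, spec$brightness[1],
                                           spec$brightness[2]), gr, gc),
                       rows, cols)
  img <- sweep(img, c(1, 2), field, "*")
  img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  pmin(pmax(img, 0), 1)
}

# Place k non-overlapping lesions; returns list(image, mask, inventory).
paint_lesions <- function(img, k, spec) {
  M <- dim(img)[1]; N <- dim(img)[2]
  mask <- matrix(FALSE, M, N)
  inv <- list()
  placed <- matrix(numeric(0), 0, 2)
  min_sep <- max(spec$lesion_size) * 1.5
  for (i in seq_len(k)) {
    for (try in seq_len(200L)) {
      cr <- stats::runif(1, spec$margin, M - spec$margin)
      cc <- stats::runif(1, spec$margin, N - spec$margin)
      if (nrow(placed) == 0L ||
          min(sqrt((placed[, 1] - cr)^2 + (placed[, 2] - cc)^2)) > min_sep) break
    }
    placed <- rbind(placed, c(cr, cc))
    d <- stats::runif(1, spec$lesion_size[1], spec$lesion_size[2])
    a <- d / 2
    b <- a * stats::runif(1, 0.7, 1)
    theta <- stats::runif(1, 0, pi)
    col <- hsv_px(stats::runif(1, spec$lesion_hue[1], spec$lesion_hue[2]),
                  stats::runif(1, spec$lesion_sat[1], spec$lesion_sat[2]),
                  stats::runif(1, spec$lesion_val[1], spec$lesion_val[2]))
    rows <- max(1L, floor(cr - a)):min(M, ceiling(cr + a))
    cols <- max(1L, floor(cc - a)):min(N, ceiling(cc + a))
    m <- ellipse_mask(rows, cols, cr, cc, a, b, theta)
    jit <- stats::runif(sum(m), 0.92, 1.08)
    for (ch in 1:3) {
      plane <- img[rows, cols, ch]
      plane[m] <- pmin(pmax(col[ch] * jit, 0), 1)
      img[rows, cols, ch] <- plane
    }
    sub <- mask[rows, cols]
    sub[m] <- TRUE
    mask[rows, cols] <- sub
    inv[[i]] <- data.frame(row = cr, col = cc, size = d)
  }
  list(image = img, mask = mask,
       inventory = if (length(inv)) do.call(rbind, inv)
                   else data.frame(row = numeric(0), col = numeric(0),
                                   size = numeric(0)))
}

#' Generate a synthetic canopy with ground truth
#'
#' Renders the canopy texture, draws the lesion count from the Poisson
#' distribution (unless `n_lesions` overrides it), paints non-overlapping
#' lesions, and snaps the image to the 8-bit lattice so PNG round-trips
#' are bit-exact. The returned mask marks exactly the painted lesion
#' pixels.
#'
#' @param spec A [canopy_spec()].
#' @param n_lesions Optional fixed lesion count overriding the Poisson
#'   draw.
#' @return An object of class `synthetic_canopy`: list with `image`
#'   (`rows x cols x 3` in `[0, 1]`), `mask` (logical matrix), `lesions`
#'   (data frame of centres and diameters) and `spec`.
#' @export
generate_canopy <- function(spec = canopy_spec(), n_lesions = NULL) {
  stopifnot(inherits(spec, "canopy_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  img <- render_canopy_texture(spec$rows, spec$cols, spec)
  k <- if (is.null(n_lesions)) stats::rpois(1, spec$lesion_mean)
       else as.integer(n_lesions)
  res <- paint_lesions(img, k, spec)
  img <- round(res$image * 255) / 255
  structure(list(image = img, mask = res$mask, lesions = res$inventory,
                 spec = spec), class = "synthetic_canopy")
}

#' @export
print.synthetic_canopy <- function(x, ...) {
  cat(sprintf("synthetic_canopy: %d x %d, %d lesion(s), %.2f%% lesion pixels\n",
              nrow(x$mask), ncol(x$mask), nrow(x$lesions), 100 * mean(x$mask)))
  invisible(x)
}

#' Synthetic single-leaf specification
#'
#' One green leaf-shaped region on a near-uniform brown background, with
#' optional lesion spots inside the leaf — the layout of class-folder
#' single-leaf disease datasets. The leaf stays clear of the image
#' corners, so the 8 x 8 corner patches used to bootstrap the
#' foreground/background separator are guaranteed background.
#'
#' @param rows,cols Image size in pixels.
#' @param leaf_frac Range of the leaf semi-axes as a fraction of the image
#'   half-size.
#' @param bg_hue,bg_sat,bg_val Background HSV ranges.
#' @param noise_sd Background/leaf pixel noise.
#' @param lesion_mean Poisson mean of the lesion spot count.
#' @param lesion_size Lesion spot diameter range in pixels.
#' @param seed RNG seed.
#' @return An object of class `leaf_spec`.
#' @export
leaf_spec <- function(rows = 256L, cols = 256L, leaf_frac = c(0.60, 0.80),
                      bg_hue = c(0.06, 0.10), bg_sat = c(0.25, 0.40),
                      bg_val = c(0.40, 0.55), noise_sd = 0.015,
                      lesion_mean = 2, lesion_size = c(6, 16), seed = NULL) {
  structure(as.list(environment()), class = "leaf_spec")
}

#' Generate a synthetic single-leaf image
#'
#' @param spec A [leaf_spec()].
#' @param n_lesions Optional fixed lesion count.
#' @return An object of class `synthetic_leaf`: `image`, `leaf_mask`,
#'   `lesion_mask` (logical matrices) and `spec`.
#' @export
generate_leaf <- function(spec = leaf_spec(), n_lesions = NULL) {
  stopifnot(inherits(spec, "leaf_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  M <- spec$rows; N <- spec$cols
  bg <- hsv_px(stats::runif(1, spec$bg_hue[1], spec$bg_hue[2]),
               stats::runif(1, spec$bg_sat[1], spec$bg_sat[2]),
               stats::runif(1, spec$bg_val[1], spec$bg_val[2]))
  img <- array(rep(bg, each = M * N), c(M, N, 3L))
  cr <- M / 2 + stats::runif(1, -6, 6)
  cc <- N / 2 + stats::runif(1, -6, 6)
  a <- stats::runif(1, spec$leaf_frac[1], spec$leaf_frac[2]) * M / 2
  b <- stats::runif(1, spec$leaf_frac[1], spec$leaf_frac[2]) * N / 2
  theta <- stats::runif(1, -0.3, 0.3)
  rows <- seq_len(M); cols <- seq_len(N)
  leaf <- ellipse_mask(rows, cols, cr, cc, a, b, theta)
  # shade the leaf with a mild radial gradient so it is not one flat colour
  leaf_col <- hsv_px(stats::runif(1, 0.26, 0.34), stats::runif(1, 0.6, 0.85),
                     stats::runif(1, 0.45, 0.7))
  dr <- matrix(rows, M, N) - cr
  dc <- matrix(cols, M, N, byrow = TRUE) - cc
  shade <- 1 - 0.25 * pmin(sqrt((dr / a)^2 + (dc / b)^2), 1)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[leaf] <- leaf_col[ch] * shade[leaf]
    img[, , ch] <- plane
  }
  k <- if (is.null(n_lesions)) stats::rpois(1, spec$lesion_mean)
       else as.integer(n_lesions)
  lesion_mask <- matrix(FALSE, M, N)
  for (i in seq_len(k)) {
    d <- stats::runif(1, spec$lesion_size[1], spec$lesion_size[2])
    for (try in seq_len(200L)) {
      lr <- stats::runif(1, 1, M); lc <- stats::runif(1, 1, N)
      # spot (incl. radius) fully inside the leaf ellipse
      u <- (cos(theta) * (lr - cr) + sin(theta) * (lc - cc)) / (a - d)
      w <- (-sin(theta) * (lr - cr) + cos(theta) * (lc - cc)) / (b - d)
      if (u^2 + w^2 <= 1) break
    }
    col <- hsv_px(stats::runif(1, 0.07, 0.12), stats::runif(1, 0.7, 0.95),
                  stats::runif(1, 0.35, 0.6))
    img <- paint_ellipse(img, lr, lc, d / 2, d / 2 * stats::runif(1, 0.7, 1),
                         stats::runif(1, 0, pi), col)
    sub <- ellipse_mask(rows, cols, lr, lc, d / 2, d / 2, 0)
    lesion_mask <- lesion_mask | (sub & leaf)
  }
  img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  structure(list(image = img, leaf_mask = leaf, lesion_mask = lesion_mask,
                 spec = spec), class = "synthetic_leaf")
}

#' Generate a labeled patch training set
#'
#' Emits `n_per_class` healthy (pure texture) and `n_per_class` lesion
#' (texture plus exactly one painted lesion) patches of `rows x cols`
#' canopy texture, either as in-memory lists or as the one-directory-per-
#' class PNG layout the classifier trainer consumes.
#'
#' @param n_per_class Patches per class.
#' @param spec A [canopy_spec()]; its `rows`/`cols` give the patch size
#'   (64 x 64 by default is obtained with
#'   `canopy_spec(rows = 64, cols = 64, margin = 8)`).
#' @param dir Optional output directory; when given, PNGs are written to
#'   `dir/healthy` and `dir/lesion` and their paths returned invisibly.
#' @param seed RNG seed.
#' @return List with `patches` (list of arrays) and `labels` (factor), or
#'   (with `dir`) the written file paths, invisibly.
#' @export
generate_patch_training_set <- function(n_per_class = 100L,
                                        spec = canopy_spec(rows = 64L,
                                                           cols = 64L,
                                                           margin = 8L),
                                        dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_class
  labels <- factor(rep(c("healthy", "lesion"), each = n_per_class),
                   levels = c("healthy", "lesion"))
  patches <- vector("list", n)
  for (i in seq_len(n)) {
    img <- render_canopy_texture(spec$rows, spec$cols, spec)
    if (labels[i] == "lesion") {
      img <- paint_lesions(img, 1L, spec)$image
    }
    patches[[i]] <- round(img * 255) / 255
  }
  if (is.null(dir)) return(list(patches = patches, labels = labels))
  paths <- character(n)
  for (cl in levels(labels)) {
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, as.character(labels[i]),
                          sprintf("patch_%04d.png", i))
    write_image(patches[[i]], paths[i])
  }
  invisible(paths)
}

#' Read a class-folder patch dataset
#'
#' Loads the one-directory-per-class layout (each class folder holding
#' PNG/TIFF/JPEG patches) into patch/label lists.
#'
#' @param dir Dataset root; every subdirectory is a class.
#' @return List with `patches` and `labels`.
#' @export
read_patch_dir <- function(dir) {
  classes <- list.dirs(dir, recursive = FALSE)
  if (!length(classes)) stop("no class subdirectories under ", dir, call. = FALSE)
  patches <- list(); labels <- character(0)
  for (cl in classes) {
    files <- list.files(cl, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        full.names = TRUE, ignore.case = TRUE)
    patches <- c(patches, lapply(files, read_image))
    labels <- c(labels, rep(basename(cl), length(files)))
  }
  list(patches = patches, labels = factor(labels))
}

#' Colour-rule oracle classifier for synthetic canopies
#'
#' A deterministic `patch_classifier` that labels a patch "lesion" exactly
#' when it contains at least `min_pixels` pixels whose hue falls in the
#' generator's lesion hue band with red exceeding green. On generator
#' output this rule is exact, which makes it the perfect-classifier stub
#' for pipeline identity tests.
#'
#' @param min_pixels Minimum count of lesion-coloured pixels.
#' @param hue_range Hue band treated as lesion colour.
#' @return A `patch_classifier`.
#' @export
oracle_patch_classifier <- function(min_pixels = 1L,
                                    hue_range = c(0.05, 0.16)) {
  force(min_pixels); force(hue_range)
  structure(list(
    input_size = NA_integer_, classes = c("healthy", "lesion"),
    predict = function(patches) {
      p <- vapply(patches, function(x) {
        x <- as_image_array(x)
        r <- x[, , 1]; g <- x[, , 2]; b <- x[, , 3]
        hsv <- grDevices::rgb2hsv(r = as.vector(r), g = as.vector(g),
                                  b = as.vector(b), maxColorValue = 1)
        hit <- hsv[1, ] >= hue_range[1] & hsv[1, ] <= hue_range[2] &
          as.vector(r) > as.vector(g) & hsv[2, ] > 0.3
        as.numeric(sum(hit) >= min_pixels)
      }, numeric(1))
      P <- cbind(1 - p, p)
      colnames(P) <- c("healthy", "lesion")
      P
    }), class = "patch_classifier")
}
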