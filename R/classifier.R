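#' Patch classifier contract
#'
#' A `patch_classifier` is any object carrying `input_size` (the square
#' side length `l` the model accepts), a class vocabulary, and a `predict`
#' routine mapping a batch of `l x l x 3` images to per-image probability
#' vectors (non-negative rows summing to 1). One classifier serves both
#' whole images and resized sub-patches, relying on the decomposition
#' principle: a crop of a canopy (or leaf) shares the feature statistics of
#' the whole, so the class of a rescaled sub-patch should agree with its
#' parent's. The constructor below trains a small dense network suitable
#' for synthetic benchmarks and unit-scale work; a production backbone
#' (e.g. a fine-tuned pretrained CNN served out of process) can be plugged
#' in by supplying any object with the same fields.
#'
#' Training uses categorical cross-entropy with Adam, early stopping and a
#' reduce-on-plateau learning-rate schedule, monitored on the validation
#' set when one is given. The default backend (`"cnn"`) is a compact
#' convolutional network — conv 5x5, ReLU, 2x2 max pool, conv 3x3, ReLU,
#' global max pool, dense softmax — whose global pooling makes the
#' detector position-invariant: a small lesion counts wherever it sits in
#' the patch. The `"mlp"` backend is a dense network over the flattened
#' resized patch, kept for cheap smoke tests.
#'
#' @param patches List of `p x p x 3` arrays (any sizes; each patch is
#'   rescaled to `input_size` by area-averaged resampling before training).
#' @param labels Factor or character vector of class labels, one per patch.
#' @param val_patches,val_labels Optional validation set (same format).
#' @param input_size Side length `l` of the network input.
#' @param backend `"cnn"` (default) or `"mlp"`.
#' @param hidden Hidden-layer widths (mlp backend only).
#' @param epochs Maximum training epochs; `0` returns an untrained (random
#'   initialisation) classifier that still emits valid probabilities.
#' @param lr Initial Adam learning rate.
#' @param seed RNG seed for initialisation and batching.
#' @param ... Further arguments passed to the internal optimiser
#'   (`patience`, `min_delta`, `lr_factor`, `lr_min`, ...).
#' @return An object of class `patch_classifier`.
#' @export
train_patch_classifier <- function(patches, labels,
                                   val_patches = NULL, val_labels = NULL,
                                   input_size = 32L,
                                   backend = c("cnn", "mlp"),
                                   hidden = c(64, 32),
                                   epochs = 60, lr = 0.01, seed = NULL, ...) {
  backend <- match.arg(backend)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("configuration error: need at least 2 classes to train", call. = FALSE)
  }
  if (!is.null(val_labels)) {
    vl <- factor(val_labels, levels = levels(labels))
    if (nlevels(droplevels(vl)) < 2L) {
      stop("configuration error: validation set must contain both classes",
           call. = FALSE)
    }
  }
  if (backend == "cnn") {
    X <- patch_batch(patches, input_size)
    Xv <- if (!is.null(val_patches)) patch_batch(val_patches, input_size)
    model <- fit_cnn(X, labels, X_val = Xv, y_val = val_labels,
                     epochs = epochs, lr = lr, seed = seed, ...)
  } else {
    X <- patch_features(patches, input_size)
    Xv <- if (!is.null(val_patches)) patch_features(val_patches, input_size)
    model <- fit_mlp(X, labels, hidden = hidden, epochs = epochs, lr = lr,
                     X_val = Xv, y_val = val_labels, seed = seed, ...)
  }
  structure(list(input_size = as.integer(input_size), backend = backend,
                 classes = model$classes, model = model),
            class = "patch_classifier")
}

# Rescale each patch to l x l x 3 and flatten into a feature row.
patch_features <- function(patches, input_size) {
  feats <- vapply(patches, function(p) {
    p <- as_image_array(p)
    if (dim(p)[1] != input_size || dim(p)[2] != input_size) {
      p <- resize_area(p, input_size, input_size)
    }
    as.vector(p)
  }, numeric(3L * input_size^2))
  t(feats)
}

# Rescale patches into an (N, l, l, 3) batch array for the CNN backend.
patch_batch <- function(patches, input_size) {
  aperm(array(t(patch_features(patches, input_size)),
              c(input_size, input_size, 3L, length(patches))),
        c(4L, 1L, 2L, 3L))
}

#' @describeIn train_patch_classifier Per-patch class probabilities; rows
#'   ordered as `newdata`, columns named by class.
#' @param object A `patch_classifier`.
#' @param newdata List of patch arrays.
#' @export
predict.patch_classifier <- function(object, newdata, ...) {
  if (is.array(newdata) && length(dim(newdata)) == 3L) newdata <- list(newdata)
  if (!is.null(object$predict)) {
    P <- object$predict(newdata)
  } else if (identical(object$backend, "cnn")) {
    P <- predict_cnn(object$model, patch_batch(newdata, object$input_size))
  } else {
    P <- predict_mlp(object$model, patch_features(newdata, object$input_size))
  }
  P
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf("patch_classifier: input %d x %d x 3, classes: %s\n",
              x$input_size, x$input_size, paste(x$classes, collapse = ", ")))
  if (!is.null(x$model$history) && nrow(x$model$history)) {
    last <- x$model$history[nrow(x$model$history), ]
    cat(sprintf("  trained %d epochs, final loss %.4f%s\n", last$epoch, last$loss,
                if (!is.na(last$val_acc))
                  sprintf(", val accuracy %.3f", last$val_acc) else ""))
  }
  invisible(x)
}

#' Fixed-probability classifier stub
#'
#' Returns a `patch_classifier` whose predictions are a constant
#' probability for the positive class, regardless of input. Useful for
#' exercising the geometry of the pipeline independently of any trained
#' model.
#'
#' @param prob Constant positive-class probability.
#' @param classes Class vocabulary; the last entry is the positive class.
#' @return A `patch_classifier`.
#' @export
classifier_stub <- function(prob = 0.5, classes = c("healthy", "lesion")) {
  force(prob); force(classes)
  structure(list(
    input_size = NA_integer_, classes = classes,
    predict = function(patches) {
      n <- length(patches)
      P <- cbind(rep(1 - prob, n), rep(prob, n))
      colnames(P) <- classes
      P
    }), class = "patch_classifier")
}

#' Classify every patch of a configuration
#'
#' Applies a classifier to each patch of a [split_image()] configuration
#' (rescaling patches to the classifier input size) and keeps the
#' probability of the class of interest, yielding the configuration of
#' probabilities on the same `k1 x k2` grid. Conceptually each patch pixel
#' carries this repeated probability; the grid is collapsed to the image
#' plane by [build_ram()].
#'
#' @param co A `patch_config` from [split_image()].
#' @param classifier A `patch_classifier` (or compatible contract).
#' @param class Class of interest: column name or index into the
#'   classifier's probability output. Defaults to the last class (the
#'   positive class for the binary canopy task).
#' @return `k1 x k2` numeric matrix of probabilities in `[0, 1]`.
#' @export
classify_configuration <- function(co, classifier, class = NULL) {
  stopifnot(inherits(co, "patch_config"))
  P <- predict(classifier, as.list(co$patches))
  if (is.null(class)) class <- ncol(P)
  matrix(P[, class], co$spec$k1, co$spec$k2)
}
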