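# Small convolutional network for patch classification: conv(5x5) -> ReLU
# -> 2x2 max pool -> conv(3x3) -> ReLU -> global max pool -> dense softmax.
# The global max pool makes the detector position-invariant, which is the
# property a lesion-anywhere-in-the-patch task needs. Convolutions are
# evaluated as im2col matrix products so training stays fast in plain R.

# X: (N, H, W, C) array -> list(cols = (N*oh*ow) x (kh*kw*C), oh, ow)
im2col <- function(X, kh, kw) {
  d <- dim(X)
  oh <- d[2] - kh + 1L; ow <- d[3] - kw + 1L
  cols <- matrix(0, d[1] * oh * ow, kh * kw * d[4])
  k <- 0L
  for (c_ in seq_len(d[4])) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    cols[, k] <- as.vector(X[, di:(di + oh - 1L), dj:(dj + ow - 1L), c_])
  }
  list(cols = cols, oh = oh, ow = ow)
}

col2im_add <- function(dcols, dims, kh, kw, oh, ow) {
  dX <- array(0, dims)
  k <- 0L
  for (c_ in seq_len(dims[4])) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    dX[, di:(di + oh - 1L), dj:(dj + ow - 1L), c_] <-
      dX[, di:(di + oh - 1L), dj:(dj + ow - 1L), c_] +
      array(dcols[, k], c(dims[1], oh, ow))
  }
  dX
}

conv_forward <- function(X, W, b) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; f <- dim(W)[4]
  ic <- im2col(X, kh, kw)
  Wm <- matrix(W, ncol = f)
  Y <- sweep(ic$cols %*% Wm, 2L, b, "+")
  list(out = array(Y, c(dim(X)[1], ic$oh, ic$ow, f)), cols = ic$cols,
       oh = ic$oh, ow = ic$ow)
}

conv_backward <- function(dY, cache, X_dims, W) {
  f <- dim(W)[4]
  dYm <- matrix(dY, ncol = f)
  dW <- array(crossprod(cache$cols, dYm), dim(W))
  db <- colSums(dYm)
  dcols <- dYm %*% t(matrix(W, ncol = f))
  dX <- col2im_add(dcols, X_dims, dim(W)[1], dim(W)[2], cache$oh, cache$ow)
  list(dX = dX, dW = dW, db = db)
}

maxpool2_forward <- function(X) {
  d <- dim(X)
  oh <- d[2] %/% 2L; ow <- d[3] %/% 2L
  slabs <- vector("list", 4L)
  q <- 0L
  for (dj in 1:2) for (di in 1:2) {
    q <- q + 1L
    slabs[[q]] <- X[, seq(di, by = 2L, length.out = oh),
                    seq(dj, by = 2L, length.out = ow), , drop = FALSE]
  }
  # argmax kept as the first slab attaining the maximum
  arg <- array(1L, dim(slabs[[1]]))
  best <- slabs[[1]]
  for (q in 2:4) {
    upd <- slabs[[q]] > best
    arg[upd] <- q
    best[upd] <- slabs[[q]][upd]
  }
  list(out = best, arg = arg, in_dims = d, oh = oh, ow = ow)
}

maxpool2_backward <- function(dY, cache) {
  dX <- array(0, cache$in_dims)
  q <- 0L
  for (dj in 1:2) for (di in 1:2) {
    q <- q + 1L
    sel <- cache$arg == q
    slab <- dX[, seq(di, by = 2L, length.out = cache$oh),
               seq(dj, by = 2L, length.out = cache$ow), , drop = FALSE]
    slab[sel] <- slab[sel] + dY[sel]
    dX[, seq(di, by = 2L, length.out = cache$oh),
       seq(dj, by = 2L, length.out = cache$ow), ] <- slab
  }
  dX
}

gmp_forward <- function(X) {
  d <- dim(X)
  flat <- array(X, c(d[1], d[2] * d[3], d[4]))
  out <- apply(flat, c(1L, 3L), max)
  arg <- apply(flat, c(1L, 3L), which.max)
  list(out = out, arg = arg, dims = d)
}

gmp_backward <- function(dY, cache) {
  d <- cache$dims
  dflat <- array(0, c(d[1], d[2] * d[3], d[4]))
  idx <- cbind(rep(seq_len(d[1]), d[4]), as.vector(cache$arg),
               rep(seq_len(d[4]), each = d[1]))
  dflat[idx] <- as.vector(dY)
  array(dflat, d)
}

cnn_init <- function(channels = 3L, f1 = 8L, f2 = 16L, classes = 2L,
                     k1 = 5L, k2 = 3L) {
  glorot <- function(dims, fan_in, fan_out) {
    s <- sqrt(6 / (fan_in + fan_out))
    array(stats::runif(prod(dims), -s, s), dims)
  }
  list(W1 = glorot(c(k1, k1, channels, f1), k1 * k1 * channels, f1),
       b1 = rep(0, f1),
       W2 = glorot(c(k2, k2, f1, f2), k2 * k2 * f1, f2),
       b2 = rep(0, f2),
       W3 = glorot(c(f2, classes), f2, classes),
       b3 = rep(0, classes))
}

cnn_forward <- function(par, X, keep = FALSE) {
  c1 <- conv_forward(X, par$W1, par$b1)
  a1 <- pmax(c1$out, 0)
  p1 <- maxpool2_forward(a1)
  c2 <- conv_forward(p1$out, par$W2, par$b2)
  a2 <- pmax(c2$out, 0)
  g <- gmp_forward(a2)
  logits <- sweep(g$out %*% par$W3, 2L, par$b3, "+")
  if (!keep) return(logits)
  list(logits = logits, c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, g = g,
       X = X)
}

cnn_backward <- function(par, fw, dlogits) {
  dW3 <- crossprod(fw$g$out, dlogits)
  db3 <- colSums(dlogits)
  dg <- dlogits %*% t(par$W3)
  da2 <- gmp_backward(dg, fw$g)
  dc2 <- da2 * (fw$c2$out > 0)
  bk2 <- conv_backward(dc2, fw$c2, dim(fw$p1$out), par$W2)
  da1 <- maxpool2_backward(bk2$dX, fw$p1)
  dc1 <- da1 * (fw$c1$out > 0)
  bk1 <- conv_backward(dc1, fw$c1, dim(fw$X), par$W1)
  list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db,
       W3 = dW3, b3 = db3)
}

# X: (N, l, l, 3); y: factor. Full-batch Adam with early stopping and
# LR-plateau reduction on the monitored loss (validation if provided).
fit_cnn <- function(X, y, X_val = NULL, y_val = NULL, f1 = 8L, f2 = 16L,
                    epochs = 60, lr = 0.01, lr_factor = 0.2, lr_min = 1e-4,
                    lr_patience = 8, patience = 10, min_delta = 0.001,
                    seed = NULL) {
  y <- as.factor(y)
  classes <- levels(y)
  if (length(classes) < 2L) {
    stop("configuration error: training data must contain at least 2 classes",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  par <- cnn_init(dim(X)[4], f1, f2, length(classes))
  Y <- diag(length(classes))[as.integer(y), , drop = FALSE]
  if (epochs < 1L) {
    return(structure(list(par = par, classes = classes, history = data.frame()),
                     class = "canopyseg_cnn"))
  }
  has_val <- !is.null(X_val)
  if (has_val) {
    y_val <- factor(y_val, levels = classes)
    Yv <- diag(length(classes))[as.integer(y_val), , drop = FALSE]
  }
  opt <- lapply(par, function(w) list(m = w * 0, v = w * 0))
  best <- list(loss = Inf, par = par)
  wait <- 0L; lr_wait <- 0L
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    fw <- cnn_forward(par, X, keep = TRUE)
    P <- row_softmax(fw$logits)
    train_loss <- cross_entropy(P, Y)
    grads <- cnn_backward(par, fw, (P - Y) / nrow(X))
    for (nm in names(par)) {
      up <- adam_step(par[[nm]], grads[[nm]], opt[[nm]], lr, ep)
      par[[nm]] <- up$par; opt[[nm]] <- up$state
    }
    if (has_val) {
      Pv <- row_softmax(cnn_forward(par, X_val))
      mon <- cross_entropy(Pv, Yv)
      val_acc <- mean(max.col(Pv) == as.integer(y_val))
    } else {
      mon <- train_loss; val_acc <- NA_real_
    }
    history[[ep]] <- data.frame(epoch = ep, loss = train_loss, monitored = mon,
                                val_acc = val_acc, lr = lr)
    if (mon < best$loss - min_delta) {
      best <- list(loss = mon, par = par)
      wait <- 0L; lr_wait <- 0L
    } else {
      wait <- wait + 1L; lr_wait <- lr_wait + 1L
      if (lr_wait >= lr_patience && lr > lr_min) {
        lr <- max(lr * lr_factor, lr_min)
        lr_wait <- 0L
      }
      if (wait >= patience) break
    }
  }
  structure(list(par = best$par, classes = classes,
                 history = do.call(rbind, history[!vapply(history, is.null, TRUE)])),
            class = "canopyseg_cnn")
}

predict_cnn <- function(model, X, batch = 512L) {
  n <- dim(X)[1]
  out <- matrix(0, n, length(model$classes))
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[idx, ] <- row_softmax(cnn_forward(model$par, X[idx, , , , drop = FALSE]))
  }
  colnames(out) <- model$classes
  out
}
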