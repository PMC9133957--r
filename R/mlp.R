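# Dense multilayer perceptron engine shared by the patch classifier and the
# leaf foreground/background separator: ReLU hidden layers, softmax output,
# categorical cross-entropy, Adam, early stopping and reduce-on-plateau
# learning-rate schedule. Kept internal; user-facing contracts wrap it.

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(t) {
    fin <- sizes[t]; fout <- sizes[t + 1L]
    s <- sqrt(6 / (fin + fout))
    list(W = matrix(stats::runif(fin * fout, -s, s), fin, fout),
         b = rep(0, fout))
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  H <- X
  for (t in seq_along(layers)) {
    Z <- H %*% layers[[t]]$W
    Z <- sweep(Z, 2L, layers[[t]]$b, "+")
    H <- if (t < length(layers)) pmax(Z, 0) else Z
    acts[[t + 1L]] <- H
  }
  list(logits = H, acts = acts)
}

row_softmax <- function(G) {
  G <- G - apply(G, 1L, max)
  E <- exp(G)
  E / rowSums(E)
}

cross_entropy <- function(P, Y) {
  -mean(rowSums(Y * log(pmax(P, 1e-12))))
}

adam_state <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(par, grad, st, lr, step, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^step)
  vhat <- st$v / (1 - beta2^step)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = st)
}

clip_global_norm <- function(grads, max_norm = 5) {
  tot <- sqrt(sum(vapply(grads, function(g) sum(g$W^2) + sum(g$b^2), numeric(1))))
  if (is.finite(tot) && tot > max_norm) {
    sc <- max_norm / tot
    grads <- lapply(grads, function(g) list(W = g$W * sc, b = g$b * sc))
  }
  grads
}

# X: n x p features; y: factor of length n. Returns list(layers, classes,
# history). Validation set drives early stopping and LR plateau reduction
# when given, otherwise the training loss does.
fit_mlp <- function(X, y, hidden = c(64, 32), epochs = 60, batch_size = 32,
                    lr = 0.1, lr_factor = 0.2, lr_min = 0.001, lr_patience = 4,
                    patience = 4, min_delta = 0.001,
                    X_val = NULL, y_val = NULL, seed = NULL) {
  y <- as.factor(y)
  classes <- levels(y)
  if (length(classes) < 2L) {
    stop("configuration error: training data must contain at least 2 classes",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  Y <- diag(length(classes))[as.integer(y), , drop = FALSE]
  layers <- mlp_init(c(ncol(X), hidden, length(classes)))
  if (epochs < 1L) {
    return(structure(list(layers = layers, classes = classes,
                          history = data.frame()), class = "canopyseg_mlp"))
  }
  has_val <- !is.null(X_val)
  if (has_val) {
    y_val <- factor(y_val, levels = classes)
    Yv <- diag(length(classes))[as.integer(y_val), , drop = FALSE]
  }
  opt <- lapply(layers, function(l) list(
    W = list(m = l$W * 0, v = l$W * 0), b = list(m = l$b * 0, v = l$b * 0)))
  best <- list(loss = Inf, layers = layers)
  wait <- 0L; lr_wait <- 0L; step <- 0L
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      fw <- mlp_forward(layers, X[idx, , drop = FALSE])
      P <- row_softmax(fw$logits)
      delta <- (P - Y[idx, , drop = FALSE]) / length(idx)
      grads <- vector("list", length(layers))
      for (t in rev(seq_along(layers))) {
        A <- fw$acts[[t]]
        grads[[t]] <- list(W = crossprod(A, delta), b = colSums(delta))
        if (t > 1L) {
          delta <- (delta %*% t(layers[[t]]$W)) * (fw$acts[[t]] > 0)
        }
      }
      grads <- clip_global_norm(grads)
      step <- step + 1L
      for (t in seq_along(layers)) {
        up <- adam_step(layers[[t]]$W, grads[[t]]$W, opt[[t]]$W, lr, step)
        layers[[t]]$W <- up$par; opt[[t]]$W <- up$state
        up <- adam_step(layers[[t]]$b, grads[[t]]$b, opt[[t]]$b, lr, step)
        layers[[t]]$b <- up$par; opt[[t]]$b <- up$state
      }
    }
    train_loss <- cross_entropy(row_softmax(mlp_forward(layers, X)$logits), Y)
    if (has_val) {
      Pv <- row_softmax(mlp_forward(layers, X_val)$logits)
      mon <- cross_entropy(Pv, Yv)
      val_acc <- mean(max.col(Pv) == as.integer(y_val))
    } else {
      mon <- train_loss
      val_acc <- NA_real_
    }
    history[[ep]] <- data.frame(epoch = ep, loss = train_loss,
                                monitored = mon, val_acc = val_acc, lr = lr)
    if (mon < best$loss - min_delta) {
      best <- list(loss = mon, layers = layers)
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
  structure(list(layers = best$layers, classes = classes,
                 history = do.call(rbind, history[!vapply(history, is.null, TRUE)])),
            class = "canopyseg_mlp")
}

predict_mlp <- function(model, X) {
  P <- row_softmax(mlp_forward(model$layers, X)$logits)
  colnames(P) <- model$classes
  P
}
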