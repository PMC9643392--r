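# Minimal dense-convnet engine. Feature maps are C x (H*W*B) matrices with
# positions p = x*H + y, columns batch-major (j = b*H*W + p); convolutions
# are stride-1 "same" via im2col + BLAS matmul, pooling is f x f averaging.
# Supported ops: conv, relu, pool, denseblock (conv-relu-concat layers),
# transition (1x1 conv-relu + pool), gap, linear.

nnForward <- function(layers, X, H, W, B, keepActs = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    op <- layers[[i]]
    if (op$type == "conv") {
      cols <- .nn_im2col(X, H, W, B, op$k)
      caches[[i]] <- list(cols = cols, H = H, W = W, Cin = nrow(X))
      X <- op$W %*% cols + op$b
    } else if (op$type == "relu") {
      mask <- X > 0
      caches[[i]] <- list(mask = mask)
      X <- X * mask
    } else if (op$type == "pool") {
      caches[[i]] <- list(H = H, W = W)
      X <- .nn_pool_fwd(X, H, W, B, op$f)
      H <- H %/% op$f; W <- W %/% op$f
    } else if (op$type == "denseblock") {
      lc <- vector("list", length(op$convs))
      for (l in seq_along(op$convs)) {
        cv <- op$convs[[l]]
        cols <- .nn_im2col(X, H, W, B, op$k)
        Yl <- cv$W %*% cols + cv$b
        mask <- Yl > 0
        lc[[l]] <- list(cols = cols, mask = mask, Cin = nrow(X))
        X <- rbind(X, Yl * mask)
      }
      caches[[i]] <- list(layers = lc, H = H, W = W,
                          out = if (keepActs) X else NULL)
    } else if (op$type == "transition") {
      Y <- op$W %*% X + op$b
      mask <- Y > 0
      caches[[i]] <- list(xin = X, mask = mask, H = H, W = W)
      X <- .nn_pool_fwd(Y * mask, H, W, B, op$f)
      H <- H %/% op$f; W <- W %/% op$f
    } else if (op$type == "gap") {
      caches[[i]] <- list(H = H, W = W)
      arr <- array(X, c(nrow(X), H * W, B))
      X <- vapply(seq_len(B), function(b) rowMeans(arr[, , b, drop = FALSE]),
                  numeric(nrow(X)))
      X <- matrix(X, nrow = dim(arr)[1], ncol = B)
    } else if (op$type == "linear") {
      caches[[i]] <- list(g = X)
      X <- matrix(as.numeric(op$W %*% X) + op$b, 1, B)
    } else stop("unknown op type: ", op$type)
  }
  list(pred = as.numeric(X), caches = caches, H = H, W = W)
}

nnBackward <- function(layers, caches, dPred, B, captureAt = NULL) {
  grads <- vector("list", length(layers))
  D <- matrix(dPred, 1, B)
  captured <- NULL
  for (i in rev(seq_along(layers))) {
    op <- layers[[i]]; ca <- caches[[i]]
    if (op$type == "linear") {
      grads[[i]] <- list(W = tcrossprod(D, ca$g), b = sum(D))
      D <- crossprod(op$W, D)
    } else if (op$type == "gap") {
      HW <- ca$H * ca$W
      D <- D[, rep(seq_len(B), each = HW), drop = FALSE] / HW
    } else if (op$type == "transition") {
      Dp <- .nn_pool_bwd(D, ca$H, ca$W, B, op$f)
      dY <- Dp * ca$mask
      grads[[i]] <- list(W = tcrossprod(dY, ca$xin), b = rowSums(dY))
      D <- crossprod(op$W, dY)
    } else if (op$type == "denseblock") {
      if (!is.null(captureAt) && captureAt == i) captured <- D
      g <- op$growth
      lg <- vector("list", length(op$convs))
      for (l in rev(seq_along(op$convs))) {
        lc <- ca$layers[[l]]
        rows <- lc$Cin + seq_len(g)
        dY <- D[rows, , drop = FALSE] * lc$mask
        lg[[l]] <- list(W = tcrossprod(dY, lc$cols), b = rowSums(dY))
        dcols <- crossprod(op$convs[[l]]$W, dY)
        dXin <- .nn_col2im(dcols, lc$Cin, ca$H, ca$W, B, op$k)
        D <- D[seq_len(lc$Cin), , drop = FALSE] + dXin
      }
      grads[[i]] <- list(convs = lg)
    } else if (op$type == "pool") {
      D <- .nn_pool_bwd(D, ca$H, ca$W, B, op$f)
    } else if (op$type == "relu") {
      D <- D * ca$mask
    } else if (op$type == "conv") {
      grads[[i]] <- list(W = tcrossprod(D, ca$cols), b = rowSums(D))
      dcols <- crossprod(op$W, D)
      D <- .nn_col2im(dcols, ca$Cin, ca$H, ca$W, B, op$k)
    }
  }
  list(grads = grads, captured = captured)
}

# AdamW: decoupled weight decay (decay applied to weights, not to the
# moment estimates); bias terms are not decayed.
adamInit <- function(layers) {
  lapply(layers, function(op) {
    zed <- function(x) list(m = array(0, dim(as.matrix(x))),
                            v = array(0, dim(as.matrix(x))))
    if (op$type %in% c("conv", "transition", "linear"))
      list(W = zed(op$W), b = zed(op$b))
    else if (op$type == "denseblock")
      list(convs = lapply(op$convs, function(cv)
        list(W = zed(cv$W), b = zed(cv$b))))
    else NULL
  })
}

adamStep <- function(layers, grads, state, lr, t, weightDecay,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(w, g, s, decay) {
    g <- as.matrix(g)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    w <- w - lr * (mh / (sqrt(vh) + eps) + decay * w)
    list(w = w, s = s)
  }
  for (i in seq_along(layers)) {
    op <- layers[[i]]; gr <- grads[[i]]
    if (is.null(gr)) next
    if (op$type == "denseblock") {
      for (l in seq_along(op$convs)) {
        r <- upd(op$convs[[l]]$W, gr$convs[[l]]$W,
                 state[[i]]$convs[[l]]$W, weightDecay)
        op$convs[[l]]$W <- r$w; state[[i]]$convs[[l]]$W <- r$s
        r <- upd(op$convs[[l]]$b, gr$convs[[l]]$b,
                 state[[i]]$convs[[l]]$b, 0)
        op$convs[[l]]$b <- as.numeric(r$w); state[[i]]$convs[[l]]$b <- r$s
      }
    } else {
      r <- upd(op$W, gr$W, state[[i]]$W, weightDecay)
      op$W <- r$w; state[[i]]$W <- r$s
      r <- upd(op$b, gr$b, state[[i]]$b, 0)
      op$b <- if (op$type == "linear") as.numeric(r$w) else as.numeric(r$w)
      state[[i]]$b <- r$s
    }
    layers[[i]] <- op
  }
  list(layers = layers, state = state)
}

# Convert a batch of H x W x 3 patches (array H,W,3,B or a list) into the
# normalized C x (H*W*B) input matrix.
patchesToInput <- function(patches, normMean, normSd) {
  if (is.list(patches))
    patches <- array(unlist(patches, use.names = FALSE),
                     dim = c(dim(patches[[1]]), length(patches)))
  d <- dim(patches)
  if (length(d) == 3) { d <- c(d, 1L); dim(patches) <- d }
  X <- matrix(aperm(patches, c(3, 1, 2, 4)), 3, d[1] * d[2] * d[4])
  (X - normMean) / normSd
}
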