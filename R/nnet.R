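# Internal machinery for the tiny convolutional backbone.
#
# The network is small enough to train on one CPU in seconds: two 3x3 valid
# convolutions with ReLU and 2x2 average pooling, a dense layer to the raw
# feature, then the L2-Norm + Scale head and a dense classification layer.
# Convolutions are computed as im2col matrix products so the heavy lifting
# is BLAS matmul; backpropagation is written out layer by layer.

# Linear indices of every 3x3 patch of an (h, w, ch) array, one patch per
# row, columns ordered: 9 in-channel offsets (rows fastest), then channels.
im2col_idx <- function(h, w, ch) {
  oh <- h - 2L; ow <- w - 2L
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  base <- oi + (oj - 1L) * h
  offs <- as.vector(outer(0:2, (0:2) * h, `+`))
  idx <- outer(base, offs, `+`)
  if (ch > 1) {
    idx <- do.call(cbind, lapply(seq_len(ch) - 1L, function(c) idx + c * h * w))
  }
  idx
}

conv_forward <- function(a, idx, K, b, oh, ow) {
  xcol <- matrix(a[idx], nrow = nrow(idx))
  z <- xcol %*% K
  z <- sweep(z, 2, b, `+`)
  list(out = array(z, c(oh, ow, ncol(K))), xcol = xcol)
}

conv_backward <- function(dout, xcol, idx, K, a_len) {
  dz <- matrix(dout, nrow = nrow(xcol))
  gK <- crossprod(xcol, dz)
  gb <- colSums(dz)
  da <- NULL
  if (a_len > 0) {
    dxcol <- tcrossprod(dz, K)
    agg <- rowsum(as.vector(dxcol), as.vector(idx))
    da <- numeric(a_len)
    da[as.integer(rownames(agg))] <- agg
  }
  list(da = da, gK = gK, gb = gb)
}

avgpool2 <- function(a) {
  d <- dim(a)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  i1 <- seq(1L, 2L * h2, 2L); j1 <- seq(1L, 2L * w2, 2L)
  (a[i1, j1, , drop = FALSE] + a[i1 + 1L, j1, , drop = FALSE] +
   a[i1, j1 + 1L, , drop = FALSE] + a[i1 + 1L, j1 + 1L, , drop = FALSE]) / 4
}

avgpool2_backward <- function(dp, in_dim) {
  da <- array(0, in_dim)
  d <- dim(dp)
  i1 <- seq(1L, 2L * d[1], 2L); j1 <- seq(1L, 2L * d[2], 2L)
  g <- dp / 4
  da[i1, j1, ] <- g
  da[i1 + 1L, j1, ] <- g
  da[i1, j1 + 1L, ] <- g
  da[i1 + 1L, j1 + 1L, ] <- g
  da
}

# Average-pool a grayscale matrix down to side x side when dimensions
# divide evenly; bilinear resize via EBImage otherwise.
downsample_gray <- function(px, side) {
  h <- nrow(px); w <- ncol(px)
  if (h == side && w == side) return(px)
  if (h %% side == 0 && w %% side == 0) {
    fh <- h %/% side; fw <- w %/% side
    m <- rowsum(px, rep(seq_len(side), each = fh))
    t(rowsum(t(m), rep(seq_len(side), each = fw))) / (fh * fw)
  } else {
    t(EBImage::imageData(EBImage::resize(EBImage::Image(t(px)), w = side, h = side)))
  }
}

# Canonical grayscale matrix from oct_image pixels (h x w) or loaded
# (h x w x 3) arrays: channels averaged.
as_gray <- function(pixels) {
  if (length(dim(pixels)) == 3) {
    (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
  } else pixels
}

# Stack an image list into the (side, side, n) tensor the tiny CNN eats.
prep_tensor <- function(images, side) {
  n <- length(images)
  X <- array(0, c(side, side, max(n, 1L)))
  for (i in seq_len(n)) {
    X[, , i] <- downsample_gray(as_gray(images[[i]]$pixels), side)
  }
  X
}

tiny_cnn_dims <- function(side) {
  o1 <- side - 2L; p1 <- o1 %/% 2L
  o2 <- p1 - 2L; p2 <- o2 %/% 2L
  list(o1 = o1, p1 = p1, o2 = o2, p2 = p2, flat = p2 * p2 * 16L)
}

# He-initialized conv/dense weights; the classification layer starts at
# zero so the initial loss is exactly the uniform-logit log C.
init_tiny_cnn <- function(side, d, n_classes, seed) {
  dims <- tiny_cnn_dims(side)
  with_seed(seed, {
    he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
    list(K1 = he(9, 8, 9), b1 = rep(0, 8),
         K2 = he(72, 16, 72), b2 = rep(0, 16),
         W3 = he(dims$flat, d, dims$flat), b3 = rep(0, d),
         Wc = matrix(0, d, n_classes), bc = rep(0, n_classes))
  })
}

# Forward pass to raw (pre-normalization) features for a (side, side, n)
# tensor; returns cached intermediates when `cache = TRUE` (training).
tiny_cnn_raw_features <- function(params, X, idx1, idx2, dims, cache = FALSE) {
  n <- dim(X)[3]
  flat <- matrix(0, n, dims$flat)
  caches <- if (cache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    c1 <- conv_forward(X[, , i], idx1, params$K1, params$b1, dims$o1, dims$o1)
    r1 <- pmax(c1$out, 0)
    p1 <- avgpool2(r1)
    c2 <- conv_forward(p1, idx2, params$K2, params$b2, dims$o2, dims$o2)
    r2 <- pmax(c2$out, 0)
    p2 <- avgpool2(r2)
    flat[i, ] <- as.vector(p2)
    if (cache) {
      caches[[i]] <- list(x1col = c1$xcol, m1 = c1$out > 0, p1 = p1,
                          x2col = c2$xcol, m2 = c2$out > 0)
    }
  }
  raw <- sweep(flat %*% params$W3, 2, params$b3, `+`)
  list(raw = raw, flat = flat, caches = caches)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# One forward/backward pass on a minibatch; returns loss, accuracy and
# gradients for every parameter.
tiny_cnn_batch_grad <- function(params, X, y, alpha, idx1, idx2, dims) {
  n <- dim(X)[3]
  fw <- tiny_cnn_raw_features(params, X, idx1, idx2, dims, cache = TRUE)
  raw <- fw$raw
  norms <- sqrt(rowSums(raw^2))
  if (any(norms == 0)) abort("zero raw feature encountered during training")
  feat <- alpha * raw / norms
  logits <- sweep(feat %*% params$Wc, 2, params$bc, `+`)
  P <- softmax_rows(logits)
  Y <- matrix(0, n, ncol(P)); Y[cbind(seq_len(n), y)] <- 1
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(n), y)] + eps))
  acc <- mean(max.col(P, ties.method = "first") == y)

  dlog <- (P - Y) / n
  gWc <- crossprod(feat, dlog)
  gbc <- colSums(dlog)
  dfeat <- tcrossprod(dlog, params$Wc)
  # back through y = alpha x / ||x||:  dx = (alpha/||x||) (g - xhat (xhat.g))
  xhat <- raw / norms
  proj <- rowSums(xhat * dfeat)
  draw <- (alpha / norms) * (dfeat - xhat * proj)
  gW3 <- crossprod(fw$flat, draw)
  gb3 <- colSums(draw)
  dflat <- tcrossprod(draw, params$W3)

  gK1 <- matrix(0, 9, 8); gb1 <- rep(0, 8)
  gK2 <- matrix(0, 72, 16); gb2 <- rep(0, 16)
  for (i in seq_len(n)) {
    ch <- fw$caches[[i]]
    dp2 <- array(dflat[i, ], c(dims$p2, dims$p2, 16L))
    dr2 <- avgpool2_backward(dp2, c(dims$o2, dims$o2, 16L))
    dc2 <- dr2 * ch$m2
    bk2 <- conv_backward(dc2, ch$x2col, idx2, params$K2,
                         dims$p1 * dims$p1 * 8L)
    gK2 <- gK2 + bk2$gK; gb2 <- gb2 + bk2$gb
    dp1 <- array(bk2$da, c(dims$p1, dims$p1, 8L))
    dr1 <- avgpool2_backward(dp1, c(dims$o1, dims$o1, 8L))
    dc1 <- dr1 * ch$m1
    bk1 <- conv_backward(dc1, ch$x1col, idx1, params$K1, 0L)
    gK1 <- gK1 + bk1$gK; gb1 <- gb1 + bk1$gb
  }
  list(loss = loss, acc = acc,
       grads = list(K1 = gK1, b1 = gb1, K2 = gK2, b2 = gb2,
                    W3 = gW3, b3 = gb3, Wc = gWc, bc = gbc))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
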