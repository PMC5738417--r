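# Minimal feed-forward CNN engine.
#
# Purpose-built for the two network families in this package (the VGG-style
# nucleus classifier and the patch-scale interpretable classifier), written
# in plain R over BLAS matrix products. Convolutions use an im2col layout
# in channels-first (C, H, W, N) arrays: the 3x3 column matrix is assembled
# from nine contiguous array slices, and the transposed scatter in the
# backward pass reuses the same slices, so no per-pixel indexing happens in
# R. Training is Adam on a weighted cross-entropy with He initialisation,
# PReLU/ReLU activations, inverted dropout, batch normalisation of the
# input, and patience-based early stopping. Everything is deterministic
# under a seed on a single device.

nn_he_init <- function(nrow_, ncol_, fan_in) {
  matrix(rnorm(nrow_ * ncol_, 0, sqrt(2 / fan_in)), nrow_, ncol_)
}

nn_layer <- function(type, ...) c(list(type = type), list(...))

# ---- conv 3x3, stride 1, pad 1 -------------------------------------------

nn_pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  out[, 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- x
  out
}

nn_im2col <- function(xpad, C, h, w) {
  col <- matrix(0, 9L * C, h * w * dim(xpad)[4])
  r <- 1L
  for (dj in 0:2) for (dk in 0:2) {
    col[r:(r + C - 1L), ] <- xpad[, (1L + dk):(h + dk), (1L + dj):(w + dj), ,
                                  drop = FALSE]
    r <- r + C
  }
  col
}

conv_fwd <- function(layer, x) {
  d <- dim(x)  # C,H,W,N
  xpad <- nn_pad1(x)
  col <- nn_im2col(xpad, d[1], d[2], d[3])
  y <- layer$W %*% col + layer$b
  list(out = array(y, c(nrow(layer$W), d[2], d[3], d[4])),
       cache = list(xpad = xpad, dims = d))
}

conv_bwd <- function(layer, dout, cache) {
  d <- cache$dims
  dy <- matrix(dout, nrow(layer$W))
  col <- nn_im2col(cache$xpad, d[1], d[2], d[3])
  dW <- tcrossprod(dy, col)
  db <- rowSums(dy)
  dcol <- crossprod(layer$W, dy)
  dxpad <- array(0, dim(cache$xpad))
  r <- 1L
  for (dj in 0:2) for (dk in 0:2) {
    dxpad[, (1L + dk):(d[2] + dk), (1L + dj):(d[3] + dj), ] <-
      dxpad[, (1L + dk):(d[2] + dk), (1L + dj):(d[3] + dj), , drop = FALSE] +
      array(dcol[r:(r + d[1] - 1L), ], c(d[1], d[2], d[3], d[4]))
    r <- r + d[1]
  }
  list(dx = dxpad[, 2:(d[2] + 1L), 2:(d[3] + 1L), , drop = FALSE],
       grads = list(W = dW, b = db))
}

# ---- 2x2 max pool, stride 2 ----------------------------------------------

pool_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[2], 2L); i2 <- seq(2L, d[2], 2L)
  j1 <- seq(1L, d[3], 2L); j2 <- seq(2L, d[3], 2L)
  s1 <- x[, i1, j1, , drop = FALSE]; s2 <- x[, i2, j1, , drop = FALSE]
  s3 <- x[, i1, j2, , drop = FALSE]; s4 <- x[, i2, j2, , drop = FALSE]
  out <- pmax(s1, s2, s3, s4)
  # first-match argmax among the four candidates
  w1 <- s1 == out
  w2 <- s2 == out & !w1
  w3 <- s3 == out & !w1 & !w2
  w4 <- !w1 & !w2 & !w3
  list(out = out, cache = list(w1 = w1, w2 = w2, w3 = w3, w4 = w4, dims = d))
}

pool_bwd <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  i1 <- seq(1L, d[2], 2L); i2 <- seq(2L, d[2], 2L)
  j1 <- seq(1L, d[3], 2L); j2 <- seq(2L, d[3], 2L)
  dx[, i1, j1, ] <- dout * cache$w1
  dx[, i2, j1, ] <- dout * cache$w2
  dx[, i1, j2, ] <- dout * cache$w3
  dx[, i2, j2, ] <- dout * cache$w4
  dx
}

# ---- forward --------------------------------------------------------------

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  penultimate <- NULL
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "bn_input") {
      if (training) {
        mu <- mean(x); va <- mean((x - mu)^2)
        net$layers[[i]]$run_mean <- 0.9 * l$run_mean + 0.1 * mu
        net$layers[[i]]$run_var <- 0.9 * l$run_var + 0.1 * va
      } else {
        mu <- l$run_mean; va <- l$run_var
      }
      xh <- (x - mu) / sqrt(va + 1e-5)
      caches[[i]] <- if (training) list(xh = xh, va = va) else NULL
      x <- l$gamma * xh + l$beta
    } else if (l$type == "conv") {
      res <- conv_fwd(l, x)
      caches[[i]] <- res$cache
      x <- res$out
    } else if (l$type == "prelu") {
      caches[[i]] <- list(x = x)
      neg <- x < 0
      x <- x * !neg + l$alpha * x * neg
    } else if (l$type == "relu") {
      caches[[i]] <- list(pos = x > 0)
      x <- pmax(x, 0)
    } else if (l$type == "pool") {
      res <- pool_fwd(x)
      caches[[i]] <- res$cache
      x <- res$out
    } else if (l$type == "gap") {
      d <- dim(x)
      caches[[i]] <- list(dims = d)
      arr <- array(x, c(d[1], d[2] * d[3], d[4]))
      x <- rowMeans(aperm(arr, c(1, 3, 2)), dims = 2)  # C x N
      if (is.null(dim(x))) x <- matrix(x, d[1], d[4])
    } else if (l$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(dims = d)
      x <- matrix(x, prod(d[-length(d)]), d[length(d)])
    } else if (l$type == "dense") {
      caches[[i]] <- list(x = x)
      x <- l$W %*% x + l$b
    } else if (l$type == "dropout") {
      if (training) {
        m <- matrix(rbinom(length(x), 1L, 1 - l$rate), nrow(x)) / (1 - l$rate)
        caches[[i]] <- list(m = m)
        x <- x * m
      }
    } else {
      abort(sprintf("unknown layer type '%s'", l$type))
    }
    if (i == net$penultimate_at %||% -1L) penultimate <- x
  }
  logits <- x
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  probs <- sweep(e, 2, colSums(e), "/")
  list(probs = probs, logits = logits, caches = caches, net = net,
       penultimate = penultimate)
}

# ---- backward -------------------------------------------------------------

nn_backward <- function(net, fwd, y_idx, class_w) {
  N <- ncol(fwd$probs)
  w <- class_w[y_idx]
  dx <- fwd$probs
  dx[cbind(y_idx, seq_len(N))] <- dx[cbind(y_idx, seq_len(N))] - 1
  dx <- sweep(dx, 2, w, "*") / sum(w)
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- fwd$caches[[i]]
    if (l$type == "conv") {
      bw <- conv_bwd(l, dx, cache)
      grads[[i]] <- bw$grads
      dx <- bw$dx
    } else if (l$type == "dense") {
      grads[[i]] <- list(W = tcrossprod(dx, cache$x), b = rowSums(dx))
      dx <- crossprod(l$W, dx)
    } else if (l$type == "prelu") {
      xx <- cache$x
      neg <- xx < 0
      grads[[i]] <- list(alpha = sum(dx * xx * neg))
      dx <- dx * (!neg + l$alpha * neg)
    } else if (l$type == "relu") {
      dx <- dx * cache$pos
    } else if (l$type == "pool") {
      dx <- pool_bwd(array(dx, dim(cache$w1)), cache)
    } else if (l$type == "gap") {
      d <- cache$dims
      dxa <- array(0, d)
      per <- d[2] * d[3]
      for (n in seq_len(d[4])) dxa[, , , n] <- dx[, n] / per
      dx <- dxa
    } else if (l$type == "flatten") {
      dx <- array(dx, cache$dims)
    } else if (l$type == "dropout") {
      if (!is.null(cache)) dx <- dx * cache$m
    } else if (l$type == "bn_input") {
      if (!is.null(cache)) {
        n <- length(dx)
        grads[[i]] <- list(gamma = sum(dx * cache$xh), beta = sum(dx))
        dxh <- dx * l$gamma
        sd_ <- sqrt(cache$va + 1e-5)
        dx <- (dxh - mean(dxh) - cache$xh * mean(dxh * cache$xh)) / sd_
      }
    }
  }
  grads
}

nn_loss <- function(probs, y_idx, class_w) {
  N <- ncol(probs)
  w <- class_w[y_idx]
  p <- pmax(probs[cbind(y_idx, seq_len(N))], 1e-12)
  sum(-w * log(p)) / sum(w)
}

# ---- Adam -----------------------------------------------------------------

nn_adam_init <- function(net) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    pn <- intersect(names(l), c("W", "b", "alpha", "gamma", "beta"))
    if (length(pn)) {
      net$layers[[i]]$adam <- lapply(setNames(nm = pn), function(p)
        list(m = l[[p]] * 0, v = l[[p]] * 0))
    }
  }
  net$adam_t <- 0L
  net
}

nn_adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  net$adam_t <- net$adam_t + 1L
  t <- net$adam_t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- net$layers[[i]]$adam[[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
      net$layers[[i]]$adam[[p]] <- st
    }
  }
  net
}

# strip optimiser state / caches for a lightweight parameter snapshot
nn_snapshot <- function(net) {
  for (i in seq_along(net$layers)) net$layers[[i]]$adam <- NULL
  net$adam_t <- NULL
  net
}
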