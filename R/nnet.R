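# Neural-network engine: 1-D convolution + batch normalization stacks
# followed by LSTM layers and a dense head, with reverse-mode gradients
# and Adam. Written against the shapes of this problem (short fixed-
# length windows, a handful of channels) and verified by finite-
# difference gradient checks in the test suite.
#
# Arrays are (batch B, time T, channels C) throughout; (B, T) pairs are
# flattened to B*T rows with batch fastest, matching R's column-major
# reshape, so a dim<- round trip is exact.

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

nn_init_layers <- function(cfg, n_channels) {
  layers <- list()
  cin <- n_channels
  k <- cfg$kernel
  for (i in seq_len(cfg$n_conv)) {
    f <- cfg$filters
    layers[[length(layers) + 1L]] <- list(
      type = "conv", k = k,
      W = glorot(k * cin, f, c(k * cin, f)), b = numeric(f))
    layers[[length(layers) + 1L]] <- list(
      type = "bn", gamma = rep(1, f), beta = numeric(f),
      rm = numeric(f), rv = rep(1, f))
    layers[[length(layers) + 1L]] <- list(type = "relu")
    cin <- f
  }
  for (i in seq_len(cfg$n_lstm)) {
    h <- cfg$lstm_units
    layers[[length(layers) + 1L]] <- list(
      type = "lstm", units = h,
      Wx = glorot(cin, 4 * h, c(cin, 4 * h)),
      Wh = glorot(h, 4 * h, c(h, 4 * h)),
      b = numeric(4 * h))
    cin <- h
  }
  n_out <- if (cfg$n_classes == 2) 1L else cfg$n_classes
  layers[[length(layers) + 1L]] <- list(
    type = "dense", W = glorot(cin, n_out, c(cin, n_out)), b = numeric(n_out))
  layers
}

sigm <- function(x) 1 / (1 + exp(-x))

# ---- forward -----------------------------------------------------------

conv_fwd <- function(layer, x) {
  d <- dim(x); B <- d[1]; T <- d[2]; C <- d[3]
  k <- layer$k; pad <- (k - 1) %/% 2
  xp <- array(0, c(B, T + k - 1, C))
  xp[, pad + seq_len(T), ] <- x
  X2 <- matrix(0, B * T, k * C)
  for (dk in seq_len(k)) {
    X2[, ((dk - 1) * C + 1):(dk * C)] <-
      `dim<-`(xp[, dk:(dk + T - 1), , drop = FALSE], c(B * T, C))
  }
  Y <- X2 %*% layer$W
  Y <- sweep(Y, 2, layer$b, `+`)
  list(out = `dim<-`(Y, c(B, T, ncol(layer$W))), cache = list(X2 = X2, dims = d))
}

conv_bwd <- function(layer, cache, dout) {
  d <- cache$dims; B <- d[1]; T <- d[2]; C <- d[3]
  k <- layer$k; pad <- (k - 1) %/% 2
  dY <- `dim<-`(dout, c(B * T, ncol(layer$W)))
  dW <- crossprod(cache$X2, dY)
  db <- colSums(dY)
  dX2 <- tcrossprod(dY, layer$W)
  dxp <- array(0, c(B, T + k - 1, C))
  for (dk in seq_len(k)) {
    dxp[, dk:(dk + T - 1), ] <- dxp[, dk:(dk + T - 1), , drop = FALSE] +
      array(dX2[, ((dk - 1) * C + 1):(dk * C)], c(B, T, C))
  }
  list(dx = dxp[, pad + seq_len(T), , drop = FALSE],
       grads = list(W = dW, b = db))
}

bn_fwd <- function(layer, x, train, eps = 1e-5, momentum = 0.9) {
  d <- dim(x)
  X <- `dim<-`(x, c(d[1] * d[2], d[3]))
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
    layer$rm <- momentum * layer$rm + (1 - momentum) * mu
    layer$rv <- momentum * layer$rv + (1 - momentum) * v
  } else {
    mu <- layer$rm; v <- layer$rv
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, inv_std, `*`)
  Y <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  list(out = `dim<-`(Y, d), layer = layer,
       cache = list(xhat = xhat, inv_std = inv_std, dims = d))
}

bn_bwd <- function(layer, cache, dout) {
  d <- cache$dims
  dY <- `dim<-`(dout, c(d[1] * d[2], d[3]))
  xhat <- cache$xhat
  N <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, layer$gamma, `*`)
  dx <- sweep(dxhat - matrix(colMeans(dxhat), N, ncol(dY), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), N, ncol(dY), byrow = TRUE),
              2, cache$inv_std, `*`)
  list(dx = `dim<-`(dx, d), grads = list(gamma = dgamma, beta = dbeta))
}

lstm_fwd <- function(layer, x) {
  d <- dim(x); B <- d[1]; T <- d[2]
  H <- layer$units
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  out <- array(0, c(B, T, H))
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    xt <- `dim<-`(x[, t, , drop = FALSE], c(B, d[3]))
    Z <- xt %*% layer$Wx + h %*% layer$Wh
    Z <- sweep(Z, 2, layer$b, `+`)
    i <- sigm(Z[, 1:H, drop = FALSE])
    f <- sigm(Z[, H + 1:H, drop = FALSE])
    g <- tanh(Z[, 2 * H + 1:H, drop = FALSE])
    o <- sigm(Z[, 3 * H + 1:H, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    hc <- tanh(cc)
    h_prev <- h
    h <- o * hc
    out[, t, ] <- h
    steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, hc = hc, h_prev = h_prev)
  }
  list(out = out, cache = list(steps = steps, dims = d))
}

lstm_bwd <- function(layer, cache, dout) {
  d <- cache$dims; B <- d[1]; T <- d[2]; C <- d[3]
  H <- layer$units
  dWx <- array(0, dim(layer$Wx)); dWh <- array(0, dim(layer$Wh))
  db <- numeric(4 * H)
  dx <- array(0, d)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    s <- cache$steps[[t]]
    dh <- `dim<-`(dout[, t, , drop = FALSE], c(B, H)) + dh_next
    dc <- dc_next + dh * s$o * (1 - s$hc^2)
    do_ <- dh * s$hc
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    dZ <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$xt, dZ)
    dWh <- dWh + crossprod(s$h_prev, dZ)
    db <- db + colSums(dZ)
    dx[, t, ] <- tcrossprod(dZ, layer$Wx)
    dh_next <- tcrossprod(dZ, layer$Wh)
    dc_next <- dc * s$f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# Forward pass through all layers. Returns output probabilities
# (B x n_out matrix), per-layer caches, and layers (BN running stats
# are updated in train mode).
nn_forward <- function(layers, x, n_classes, train = TRUE) {
  caches <- vector("list", length(layers))
  last_lstm <- max(c(0L, which(vapply(layers, `[[`, "", "type") == "lstm")))
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type == "conv") {
      r <- conv_fwd(l, x); x <- r$out; caches[[li]] <- r$cache
    } else if (l$type == "bn") {
      r <- bn_fwd(l, x, train); x <- r$out; caches[[li]] <- r$cache
      layers[[li]] <- r$layer
    } else if (l$type == "relu") {
      caches[[li]] <- x > 0
      x <- x * (x > 0)
    } else if (l$type == "lstm") {
      r <- lstm_fwd(l, x); caches[[li]] <- r$cache
      if (li == last_lstm) {
        x <- `dim<-`(r$out[, dim(r$out)[2], , drop = FALSE],
                     c(dim(r$out)[1], l$units))      # final hidden state
      } else x <- r$out
    } else if (l$type == "dense") {
      if (length(dim(x)) == 3) {
        # CNN-only architecture: global average pooling over time
        dims3 <- dim(x)
        x2 <- `dim<-`(colMeans(aperm(x, c(2, 1, 3))), c(dims3[1], dims3[3]))
        caches[[li]] <- list(h = x2, pooled = TRUE, dims = dims3)
        x <- x2
      } else {
        caches[[li]] <- list(h = x, pooled = FALSE)
      }
      x <- sweep(x %*% l$W, 2, l$b, `+`)
    }
  }
  logits <- x
  probs <- if (n_classes == 2) {
    sigm(logits)
  } else {
    e <- exp(logits - apply(logits, 1, max))
    e / rowSums(e)
  }
  list(probs = probs, logits = logits, caches = caches, layers = layers)
}

# Cross-entropy loss (binary with a single sigmoid logit when
# n_classes == 2, categorical softmax otherwise) with per-sample
# weights and L2 penalty on convolution kernels; returns loss and
# parameter gradients.
nn_loss_grad <- function(layers, x, y_idx, n_classes, sample_w, l2) {
  B <- dim(x)[1]
  fw <- nn_forward(layers, x, n_classes, train = TRUE)
  layers <- fw$layers
  eps <- 1e-12
  if (n_classes == 2) {
    p <- fw$probs[, 1]
    yb <- as.numeric(y_idx == 2L)     # class 2 = positive
    loss <- -mean(sample_w * (yb * log(p + eps) + (1 - yb) * log(1 - p + eps)))
    dlogits <- matrix(sample_w * (p - yb) / B, ncol = 1)
  } else {
    py <- fw$probs[cbind(seq_len(B), y_idx)]
    loss <- -mean(sample_w * log(py + eps))
    dlogits <- fw$probs
    dlogits[cbind(seq_len(B), y_idx)] <- dlogits[cbind(seq_len(B), y_idx)] - 1
    dlogits <- dlogits * sample_w / B
  }
  grads <- vector("list", length(layers))
  dout <- dlogits
  last_lstm <- max(c(0L, which(vapply(layers, `[[`, "", "type") == "lstm")))
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    if (l$type == "dense") {
      ch <- fw$caches[[li]]
      grads[[li]] <- list(W = crossprod(ch$h, dout), b = colSums(dout))
      dout <- tcrossprod(dout, l$W)
      if (ch$pooled) {
        dims3 <- ch$dims
        dseq <- array(0, dims3)
        for (t in seq_len(dims3[2])) dseq[, t, ] <- dout / dims3[2]
        dout <- dseq
      }
    } else if (l$type == "lstm") {
      if (li == last_lstm) {
        # gradient only flows into the final time step
        dims <- fw$caches[[li]]$dims
        dseq <- array(0, c(dims[1], dims[2], l$units))
        dseq[, dims[2], ] <- dout
        dout <- dseq
      }
      r <- lstm_bwd(l, fw$caches[[li]], dout)
      grads[[li]] <- r$grads; dout <- r$dx
    } else if (l$type == "relu") {
      dout <- dout * fw$caches[[li]]
    } else if (l$type == "bn") {
      r <- bn_bwd(l, fw$caches[[li]], dout)
      grads[[li]] <- r$grads; dout <- r$dx
    } else if (l$type == "conv") {
      r <- conv_bwd(l, fw$caches[[li]], dout)
      r$grads$W <- r$grads$W + 2 * l2 * l$W   # weight decay on conv kernels
      loss <- loss + l2 * sum(l$W^2)
      grads[[li]] <- r$grads; dout <- r$dx
    }
  }
  list(loss = loss, grads = grads, layers = layers, probs = fw$probs)
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- intersect(names(l), c("W", "b", "Wx", "Wh", "gamma", "beta"))
    st <- lapply(l[nm], function(p) list(m = p * 0, v = p * 0))
    st
  })
}

adam_step <- function(layers, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- opt[[li]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[li]][[nm]] <- layers[[li]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      opt[[li]][[nm]] <- st
    }
  }
  list(layers = layers, opt = opt)
}

# Analytic parameter count for a config (trainable parameters:
# conv kernels + biases, BN scale/shift, LSTM input/recurrent/bias,
# dense head).
count_parameters <- function(cfg, n_channels) {
  total <- 0
  cin <- n_channels
  for (i in seq_len(cfg$n_conv)) {
    total <- total + cfg$kernel * cin * cfg$filters + cfg$filters + 2 * cfg$filters
    cin <- cfg$filters
  }
  for (i in seq_len(cfg$n_lstm)) {
    h <- cfg$lstm_units
    total <- total + 4 * (cin * h + h * h + h)
    cin <- h
  }
  n_out <- if (cfg$n_classes == 2) 1 else cfg$n_classes
  total + cin * n_out + n_out
}

n_parameters_layers <- function(layers) {
  sum(vapply(layers, function(l) {
    nm <- intersect(names(l), c("W", "b", "Wx", "Wh", "gamma", "beta"))
    sum(vapply(l[nm], length, numeric(1)))
  }, numeric(1)))
}
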