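# Minimal convolutional-network engine used by the tiny_cnn fragment
# classifier: NHWC tensors, 3x3 same-padding convolutions implemented as
# nine shifted matrix products, 2x2 max pooling, a single-logit dense head,
# binary cross-entropy with logits, and Adam. Written to be exactly
# differentiable-checkable (see the finite-difference test) rather than
# fast on GPUs; batches of a few hundred 32 px fragments train in seconds.

nn_init <- function(input_size = 32L, in_channels = 3L,
                    channels = c(8L, 16L, 32L), seed = 1L) {
  if (input_size %% (2^length(channels)) != 0L) {
    stop("input size must be divisible by 2^n_conv_blocks")
  }
  local_seed(seed, {
    params <- list()
    cin <- in_channels
    for (l in seq_along(channels)) {
      cout <- channels[l]
      fan_in <- 9L * cin
      params[[paste0("W", l)]] <- array(
        rnorm(9L * cin * cout, 0, sqrt(2 / fan_in)), dim = c(3L, 3L, cin, cout)
      )
      params[[paste0("b", l)]] <- numeric(cout)
      cin <- cout
    }
    flat <- (input_size / 2^length(channels))^2 * cin
    params$Wd <- matrix(rnorm(flat, 0, sqrt(2 / flat)), flat, 1L)
    params$bd <- 0
    list(params = params, input_size = input_size,
         in_channels = in_channels, channels = channels)
  })
}

# x: array (n, h, w, c); W: (3, 3, cin, cout); same padding, stride 1.
.conv_forward <- function(x, W, b) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; cin <- d[4]
  cout <- dim(W)[4]
  xp <- array(0, dim = c(n, h + 2L, w + 2L, cin))
  xp[, 2:(h + 1), 2:(w + 1), ] <- x
  y <- matrix(rep(b, each = n * h * w), n * h * w, cout)
  for (di in 0:2) {
    for (dj in 0:2) {
      s <- xp[, di + seq_len(h), dj + seq_len(w), , drop = FALSE]
      sm <- matrix(s, n * h * w, cin)
      y <- y + sm %*% matrix(W[di + 1, dj + 1, , ], cin, cout)
    }
  }
  list(out = array(y, dim = c(n, h, w, cout)), xp = xp)
}

.conv_backward <- function(dy, cache, W) {
  xp <- cache$xp
  d <- dim(xp); n <- d[1]; h <- d[2] - 2L; w <- d[3] - 2L; cin <- d[4]
  cout <- dim(W)[4]
  dym <- matrix(dy, n * h * w, cout)
  dW <- array(0, dim = dim(W))
  dxp <- array(0, dim = dim(xp))
  for (di in 0:2) {
    for (dj in 0:2) {
      s <- xp[, di + seq_len(h), dj + seq_len(w), , drop = FALSE]
      sm <- matrix(s, n * h * w, cin)
      dW[di + 1, dj + 1, , ] <- crossprod(sm, dym)
      dxm <- tcrossprod(dym, matrix(W[di + 1, dj + 1, , ], cin, cout))
      dxp[, di + seq_len(h), dj + seq_len(w), ] <-
        dxp[, di + seq_len(h), dj + seq_len(w), , drop = FALSE] +
        array(dxm, dim = c(n, h, w, cin))
    }
  }
  db <- colSums(dym)
  list(dx = dxp[, 2:(h + 1), 2:(w + 1), , drop = FALSE], dW = dW, db = db)
}

.pool_forward <- function(x) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  ho <- h %/% 2L; wo <- w %/% 2L
  slabs <- list(
    x[, seq(1, h, 2), seq(1, w, 2), , drop = FALSE],
    x[, seq(1, h, 2), seq(2, w, 2), , drop = FALSE],
    x[, seq(2, h, 2), seq(1, w, 2), , drop = FALSE],
    x[, seq(2, h, 2), seq(2, w, 2), , drop = FALSE]
  )
  out <- pmax(slabs[[1]], slabs[[2]], slabs[[3]], slabs[[4]])
  list(out = out, slabs = slabs, in_dim = d)
}

.pool_backward <- function(dy, cache) {
  d <- cache$in_dim; n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  out <- pmax(cache$slabs[[1]], cache$slabs[[2]],
              cache$slabs[[3]], cache$slabs[[4]])
  dx <- array(0, dim = d)
  assigned <- array(FALSE, dim = dim(out))
  idx <- list(
    list(seq(1, h, 2), seq(1, w, 2)), list(seq(1, h, 2), seq(2, w, 2)),
    list(seq(2, h, 2), seq(1, w, 2)), list(seq(2, h, 2), seq(2, w, 2))
  )
  for (k in 1:4) {
    take <- (cache$slabs[[k]] == out) & !assigned
    assigned <- assigned | take
    dx[, idx[[k]][[1]], idx[[k]][[2]], ] <- dy * take
  }
  dx
}

nn_forward <- function(net, x, with_cache = FALSE) {
  params <- net$params
  caches <- list()
  a <- x
  for (l in seq_along(net$channels)) {
    cv <- .conv_forward(a, params[[paste0("W", l)]], params[[paste0("b", l)]])
    relu_mask <- cv$out > 0
    a <- cv$out * relu_mask
    pl <- .pool_forward(a)
    a <- pl$out
    if (with_cache) caches[[l]] <- list(conv = cv, relu = relu_mask, pool = pl)
  }
  n <- dim(a)[1]
  flat <- matrix(a, n, length(a) / n)
  z <- drop(flat %*% params$Wd) + params$bd
  if (with_cache) list(z = z, caches = caches, flat = flat, a_dim = dim(a))
  else list(z = z)
}

# mean BCE-with-logits and its gradient wrt z
nn_loss <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

nn_backward <- function(net, fwd, y) {
  params <- net$params
  n <- length(fwd$z)
  dz <- (1 / (1 + exp(-fwd$z)) - y) / n
  grads <- list(
    Wd = crossprod(fwd$flat, matrix(dz, n, 1)),
    bd = sum(dz)
  )
  da <- array(matrix(dz, n, 1) %*% t(params$Wd), dim = fwd$a_dim)
  for (l in rev(seq_along(net$channels))) {
    cache <- fwd$caches[[l]]
    da <- .pool_backward(da, cache$pool)
    da <- da * cache$relu
    bw <- .conv_backward(da, cache$conv, params[[paste0("W", l)]])
    grads[[paste0("W", l)]] <- bw$dW
    grads[[paste0("b", l)]] <- bw$db
    da <- bw$dx
  }
  grads
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Bilinear resize of one h x w x 3 raster to size x size.
resize_rgb <- function(arr, size) {
  d <- dim(arr)
  if (d[1] == size && d[2] == size) return(arr / 1)
  map_axis <- function(n_in) {
    src <- (seq_len(size) - 0.5) * n_in / size - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    i0 <- pmin(floor(src), n_in - 2)
    list(i0 = i0 + 1, w = src - i0)
  }
  ry <- map_axis(d[1]); rx <- map_axis(d[2])
  out <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    a <- arr[, , ch]
    i0 <- rep(ry$i0, size); j0 <- rep(rx$i0, each = size)
    wy <- rep(ry$w, size); wx <- rep(rx$w, each = size)
    v <- (1 - wy) * (1 - wx) * a[cbind(i0, j0)] +
      (1 - wy) * wx * a[cbind(i0, j0 + 1)] +
      wy * (1 - wx) * a[cbind(i0 + 1, j0)] +
      wy * wx * a[cbind(i0 + 1, j0 + 1)]
    out[, , ch] <- matrix(v, size, size)
  }
  out
}
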