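# Compact convolutional network engine.
#
# A small, dependency-free CNN sufficient for the border-irregularity
# classifier: 3x3 "same" convolutions (im2col + BLAS GEMM), 2x2 max pooling,
# dense layers, sigmoid output, binary cross-entropy, Adam. Everything is
# deterministic given the cnn_spec seed.

#' CNN architecture and training specification
#'
#' Describes the border classifier network: five 3x3 convolution layers
#' (ReLU), each followed by 2x2 max pooling, then two dense layers (ReLU,
#' then a single sigmoid unit). The network input is the smoothed segmented
#' image and the border map stacked as two channels; the 27-value
#' irregularity descriptor is concatenated onto the flattened convolutional
#' features before the first dense layer. Training uses binary cross-entropy
#' with Adam.
#'
#' @param input_size Square input side in pixels; must be divisible by
#'   `2^length(filters)`. 128 is the desk-scale default (a flag up to 512 is
#'   supported).
#' @param filters Feature-map counts of the five convolution layers.
#' @param dense_units Width of the penultimate dense layer.
#' @param n_features Length of the auxiliary descriptor vector.
#' @param lr Adam learning rate.
#' @param epochs Training epochs (the reference configuration trains briefly;
#'   default 1).
#' @param batch_size Mini-batch size.
#' @param seed Integer seed governing initialization and shuffling.
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(input_size = 128, filters = c(16, 32, 64, 128, 256),
                     dense_units = 64, n_features = 27, lr = 0.001,
                     epochs = 1, batch_size = 8, seed = 1) {
  if (input_size %% 2^length(filters) != 0) {
    abort(sprintf("input_size must be divisible by %d", 2^length(filters)))
  }
  structure(
    list(input_size = as.integer(input_size), channels = 2L,
         filters = as.integer(filters), kernel = 3L, pool = 2L,
         dense_units = as.integer(dense_units),
         n_features = as.integer(n_features), lr = lr,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "cnn_spec"
  )
}

# ---- array plumbing ---------------------------------------------------------

# im2col for a (H, W, C, B) array with 'same' zero padding and 3x3 kernels:
# returns a (H*W*B) x (k*k*C) matrix; rows ordered (h, w, b), columns (di, dj, c).
cnn_im2col <- function(x, k = 3L) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; B <- d[4L]
  p <- (k - 1L) %/% 2L
  xp <- array(0, dim = c(H + 2L * p, W + 2L * p, C, B))
  xp[p + seq_len(H), p + seq_len(W), , ] <- x
  cols <- vector("list", k * k * C)
  i <- 1L
  for (c in seq_len(C)) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        cols[[i]] <- as.vector(xp[di + seq_len(H) - 1L, dj + seq_len(W) - 1L, c, ])
        i <- i + 1L
      }
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "geom") <- c(H = H, W = W, C = C, B = B, k = k)
  out
}

# scatter-add of a column-matrix gradient back to the (H, W, C, B) input
cnn_col2im <- function(dcol, geom) {
  H <- geom["H"]; W <- geom["W"]; C <- geom["C"]; B <- geom["B"]; k <- geom["k"]
  p <- (k - 1L) %/% 2L
  gp <- array(0, dim = c(H + 2L * p, W + 2L * p, C, B))
  i <- 1L
  for (c in seq_len(C)) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        blk <- gp[di + seq_len(H) - 1L, dj + seq_len(W) - 1L, c, , drop = FALSE]
        gp[di + seq_len(H) - 1L, dj + seq_len(W) - 1L, c, ] <-
          blk + array(dcol[, i], dim = c(H, W, 1L, B))
        i <- i + 1L
      }
    }
  }
  gp[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
}

# (H*W*B) x F matrix -> (H, W, F, B) array
rows_to_array <- function(m, H, W, B) {
  aperm(array(m, dim = c(H, W, B, ncol(m))), c(1L, 2L, 4L, 3L))
}
# (H, W, F, B) array -> (H*W*B) x F matrix
array_to_rows <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
}

# 2x2 max pooling with tie-normalized routing masks for the backward pass
cnn_maxpool <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[1L], by = 2L)
  ci <- seq(1L, d[2L], by = 2L)
  s <- list(x[ri, ci, , , drop = FALSE], x[ri + 1L, ci, , , drop = FALSE],
            x[ri, ci + 1L, , , drop = FALSE], x[ri + 1L, ci + 1L, , , drop = FALSE])
  m <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  ties <- (s[[1L]] == m) + (s[[2L]] == m) + (s[[3L]] == m) + (s[[4L]] == m)
  list(out = m, slices = s, max = m, ties = ties, dim = d)
}

cnn_maxpool_backward <- function(pool, dout) {
  d <- pool$dim
  dx <- array(0, dim = d)
  ri <- seq(1L, d[1L], by = 2L)
  ci <- seq(1L, d[2L], by = 2L)
  g <- dout / pool$ties
  dx[ri, ci, , ] <- g * (pool$slices[[1L]] == pool$max)
  dx[ri + 1L, ci, , ] <- g * (pool$slices[[2L]] == pool$max)
  dx[ri, ci + 1L, , ] <- g * (pool$slices[[3L]] == pool$max)
  dx[ri + 1L, ci + 1L, , ] <- g * (pool$slices[[4L]] == pool$max)
  dx
}

# ---- model ------------------------------------------------------------------

cnn_init <- function(spec) {
  k <- spec$kernel
  chans <- c(spec$channels, spec$filters)
  layers <- vector("list", length(spec$filters))
  for (l in seq_along(spec$filters)) {
    fan_in <- k * k * chans[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * chans[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, chans[l + 1L]),
      b = numeric(chans[l + 1L])
    )
  }
  spatial <- spec$input_size / 2^length(spec$filters)
  flat <- spatial^2 * spec$filters[length(spec$filters)] + spec$n_features
  dense1 <- list(
    W = matrix(stats::rnorm(flat * spec$dense_units, sd = sqrt(2 / flat)),
               flat, spec$dense_units),
    b = numeric(spec$dense_units)
  )
  dense2 <- list(
    W = matrix(stats::rnorm(spec$dense_units, sd = sqrt(1 / spec$dense_units)),
               spec$dense_units, 1L),
    b = 0
  )
  list(conv = layers, dense1 = dense1, dense2 = dense2, spatial = spatial,
       n_features = spec$n_features)
}

cnn_forward <- function(model, x, feats, keep = FALSE) {
  B <- dim(x)[4L]
  cache <- list()
  a <- x
  for (l in seq_along(model$conv)) {
    col <- cnn_im2col(a, 3L)
    z <- sweep(col %*% model$conv[[l]]$W, 2L, model$conv[[l]]$b, "+")
    r <- z
    r[r < 0] <- 0
    act <- rows_to_array(r, dim(a)[1L], dim(a)[2L], B)
    pool <- cnn_maxpool(act)
    if (keep) cache[[l]] <- list(col = col, geom = attr(col, "geom"),
                                 relu = r, pool = pool)
    a <- pool$out
  }
  flat <- t(apply(a, 4L, as.vector)) # B x (spatial^2 * F)
  if (B == 1L) flat <- matrix(as.vector(a), 1L)
  flat <- cbind(flat, feats)
  z1 <- sweep(flat %*% model$dense1$W, 2L, model$dense1$b, "+")
  h1 <- z1
  h1[h1 < 0] <- 0
  z2 <- as.vector(h1 %*% model$dense2$W) + model$dense2$b
  s <- 1 / (1 + exp(-z2))
  list(s = s, cache = cache, flat = flat, h1 = h1, z1 = z1, a_last = a)
}

cnn_backward <- function(model, fwd, y) {
  B <- length(y)
  dz2 <- (fwd$s - y) / B # BCE + sigmoid
  g <- list()
  g$dense2_W <- t(fwd$h1) %*% matrix(dz2, B, 1L)
  g$dense2_b <- sum(dz2)
  dh1 <- matrix(dz2, B, 1L) %*% t(model$dense2$W)
  dz1 <- dh1 * (fwd$z1 > 0)
  g$dense1_W <- t(fwd$flat) %*% dz1
  g$dense1_b <- colSums(dz1)
  dflat <- dz1 %*% t(model$dense1$W)
  img_dim <- ncol(fwd$flat) - model$n_features
  dimg <- dflat[, seq_len(img_dim), drop = FALSE]
  d <- dim(fwd$a_last)
  da <- array(t(dimg), dim = d) # inverse of per-sample as.vector flatten
  g$conv <- vector("list", length(model$conv))
  for (l in rev(seq_along(model$conv))) {
    cc <- fwd$cache[[l]]
    dpooled <- da
    dact <- cnn_maxpool_backward(cc$pool, dpooled)
    dr <- array_to_rows(dact)
    dr[cc$relu <= 0] <- 0
    g$conv[[l]] <- list(W = t(cc$col) %*% dr, b = colSums(dr))
    if (l > 1L) {
      dcol <- dr %*% t(model$conv[[l]]$W)
      da <- cnn_col2im(dcol, cc$geom)
    }
  }
  g
}

adam_state <- function(model) {
  zero_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  list(
    conv = lapply(model$conv, function(l) list(mW = zero_like(l$W), vW = zero_like(l$W),
                                               mb = zero_like(l$b), vb = zero_like(l$b))),
    dense1 = list(mW = zero_like(model$dense1$W), vW = zero_like(model$dense1$W),
                  mb = zero_like(model$dense1$b), vb = zero_like(model$dense1$b)),
    dense2 = list(mW = zero_like(model$dense2$W), vW = zero_like(model$dense2$W),
                  mb = 0, vb = 0),
    t = 0L
  )
}

adam_update <- function(p, gpar, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8, t = 1L) {
  st$m <- b1 * st$m + (1 - b1) * gpar
  st$v <- b2 * st$v + (1 - b2) * gpar^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = st$m, v = st$v)
}

cnn_apply_grads <- function(model, g, opt, lr) {
  opt$t <- opt$t + 1L
  t <- opt$t
  upd <- function(p, gpar, m, v) {
    r <- adam_update(p, gpar, list(m = m, v = v), lr, t = t)
    r
  }
  for (l in seq_along(model$conv)) {
    r <- upd(model$conv[[l]]$W, g$conv[[l]]$W, opt$conv[[l]]$mW, opt$conv[[l]]$vW)
    model$conv[[l]]$W <- r$p; opt$conv[[l]]$mW <- r$m; opt$conv[[l]]$vW <- r$v
    r <- upd(model$conv[[l]]$b, g$conv[[l]]$b, opt$conv[[l]]$mb, opt$conv[[l]]$vb)
    model$conv[[l]]$b <- r$p; opt$conv[[l]]$mb <- r$m; opt$conv[[l]]$vb <- r$v
  }
  r <- upd(model$dense1$W, g$dense1_W, opt$dense1$mW, opt$dense1$vW)
  model$dense1$W <- r$p; opt$dense1$mW <- r$m; opt$dense1$vW <- r$v
  r <- upd(model$dense1$b, g$dense1_b, opt$dense1$mb, opt$dense1$vb)
  model$dense1$b <- r$p; opt$dense1$mb <- r$m; opt$dense1$vb <- r$v
  r <- upd(model$dense2$W, g$dense2_W, opt$dense2$mW, opt$dense2$vW)
  model$dense2$W <- r$p; opt$dense2$mW <- r$m; opt$dense2$vW <- r$v
  r <- upd(model$dense2$b, g$dense2_b, opt$dense2$mb, opt$dense2$vb)
  model$dense2$b <- r$p; opt$dense2$mb <- r$m; opt$dense2$vb <- r$v
  list(model = model, opt = opt)
}

# assemble the (H, W, 2, B) input tensor from image/border matrix lists
cnn_stack_inputs <- function(images, borders, size) {
  B <- length(images)
  x <- array(0, dim = c(size, size, 2L, B))
  for (i in seq_len(B)) {
    x[, , 1L, i] <- resize_image(images[[i]] / 255, size, "bilinear")
    x[, , 2L, i] <- resize_image(as_binary_mask(borders[[i]]), size, "nearest")
  }
  x
}
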