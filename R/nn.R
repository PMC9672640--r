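# Minimal convolutional-network core.
#
# No deep-learning framework is available to R in this stack, so the few
# layer types the backbones need (3x3-style convolution, ReLU, max pooling,
# global average pooling) are implemented here directly on base-R arrays.
# Convolution is lowered to a BLAS matrix product via im2col; backward
# passes reuse the same index machinery. Arrays are laid out [H, W, C, N]
# (column-major, image index last) so that per-image blocks are contiguous.

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L) {
  list(type = "conv", in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       W = NULL, b = NULL)
}
nn_relu <- function() list(type = "relu")
nn_maxpool <- function(k = 2L, stride = k) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride))
}

# He-normal init; biases zero. Deterministic given the current RNG state.
nn_init_layers <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      fan_in <- l$in_ch * l$k * l$k
      l$W <- matrix(stats::rnorm(l$out_ch * fan_in, sd = sqrt(2 / fan_in)),
                    nrow = l$out_ch)
      l$b <- numeric(l$out_ch)
      layers[[i]] <- l
    }
  }
  layers
}

# im2col index matrix for one [H2, W2, C] image: rows are the k*k*C patch
# entries (dh fastest, then dw, then channel), columns the output positions
# (output row fastest). Values are 1-based linear indices into the image.
im2col_index <- function(H2, W2, C, k, stride) {
  Ho <- (H2 - k) %/% stride + 1L
  Wo <- (W2 - k) %/% stride + 1L
  dh <- rep(seq_len(k) - 1L, times = k * C)
  dw <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  dc <- rep(seq_len(C) - 1L, each = k * k)
  patch_off <- dh + dw * H2 + dc * (H2 * W2) + 1L
  pos_off <- rep((seq_len(Ho) - 1L) * stride, times = Wo) +
    rep((seq_len(Wo) - 1L) * stride * H2, each = Ho)
  list(idx = outer(patch_off, pos_off, `+`), Ho = Ho, Wo = Wo)
}

pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

conv_forward <- function(x, l, train = FALSE) {
  xp <- pad_input(x, l$pad)
  d <- dim(xp)
  if (d[3] != l$in_ch) stop_invalid("conv layer expects ", l$in_ch,
                                    " input channels, got ", d[3])
  ii <- im2col_index(d[1], d[2], d[3], l$k, l$stride)
  N <- d[4]
  img_off <- (seq_len(N) - 1L) * (d[1] * d[2] * d[3])
  IDX <- outer(as.vector(ii$idx), img_off, `+`)
  X <- matrix(xp[IDX], nrow = l$k * l$k * l$in_ch)
  Y <- l$W %*% X + l$b
  out <- aperm(array(Y, dim = c(l$out_ch, ii$Ho, ii$Wo, N)), c(2, 3, 1, 4))
  cache <- if (train) list(xp_dim = d, pad = l$pad, xp = xp) else NULL
  list(out = out, cache = cache)
}

conv_backward <- function(dout, l, cache) {
  d <- cache$xp_dim
  ii <- im2col_index(d[1], d[2], d[3], l$k, l$stride)
  N <- d[4]
  img_off <- (seq_len(N) - 1L) * (d[1] * d[2] * d[3])
  IDX <- outer(as.vector(ii$idx), img_off, `+`)
  X <- matrix(cache$xp[IDX], nrow = l$k * l$k * l$in_ch)
  dY <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = l$out_ch)
  dW <- dY %*% t(X)
  db <- rowSums(dY)
  dXc <- crossprod(l$W, dY)
  dxp <- array(0, dim = d)
  nr <- nrow(ii$idx)
  IDX <- matrix(IDX, nrow = nr)
  for (r in seq_len(nr)) {
    # indices within one patch-offset row are distinct for stride >= 1
    i <- IDX[r, ]
    dxp[i] <- dxp[i] + dXc[r, ]
  }
  p <- l$pad
  dx <- if (p > 0L)
    dxp[p + seq_len(d[1] - 2L * p), p + seq_len(d[2] - 2L * p), , , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

maxpool_forward <- function(x, l, train = FALSE) {
  d <- dim(x)
  ii <- im2col_index(d[1], d[2], 1L, l$k, l$stride)
  nplane <- d[3] * d[4]
  plane_off <- (seq_len(nplane) - 1L) * (d[1] * d[2])
  IDX <- matrix(outer(as.vector(ii$idx), plane_off, `+`), nrow = l$k * l$k)
  X <- matrix(x[IDX], nrow = l$k * l$k)
  best <- X[1, ]
  sel <- rep(1L, ncol(X))
  for (r in seq_len(nrow(X))[-1]) {
    upd <- X[r, ] > best
    best[upd] <- X[r, upd]
    sel[upd] <- r
  }
  out <- array(best, dim = c(ii$Ho, ii$Wo, d[3], d[4]))
  cache <- if (train) list(in_dim = d, sel = sel) else NULL
  list(out = out, cache = cache)
}

maxpool_backward <- function(dout, l, cache) {
  d <- cache$in_dim
  ii <- im2col_index(d[1], d[2], 1L, l$k, l$stride)
  nplane <- d[3] * d[4]
  plane_off <- (seq_len(nplane) - 1L) * (d[1] * d[2])
  IDX <- matrix(outer(as.vector(ii$idx), plane_off, `+`), nrow = l$k * l$k)
  win <- IDX[cbind(cache$sel, seq_along(cache$sel))]
  dv <- as.vector(dout)
  dx <- numeric(prod(d))
  # overlapping windows (k > stride) can route several gradients to one voxel
  agg <- rowsum(dv, group = win)
  dx[as.integer(rownames(agg))] <- agg
  array(dx, dim = d)
}

# Forward through a layer stack. x: [H, W, C, N]. With train = TRUE the
# per-layer caches needed by nn_backward are kept.
nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- conv_forward(x, l, train)
      x <- r$out; caches[[i]] <- r$cache
    } else if (l$type == "relu") {
      if (train) caches[[i]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (l$type == "maxpool") {
      r <- maxpool_forward(x, l, train)
      x <- r$out; caches[[i]] <- r$cache
    } else stop_invalid("unknown layer type: ", l$type)
  }
  list(out = x, caches = caches)
}

# Backward through the stack; returns per-layer parameter gradients
# (NULL for parameter-free layers) and the input gradient.
nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- conv_backward(dout, l, caches[[i]])
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dout <- r$dx
    } else if (l$type == "relu") {
      dout <- dout * caches[[i]]$mask
    } else if (l$type == "maxpool") {
      dout <- maxpool_backward(dout, l, caches[[i]])
    }
  }
  list(grads = grads, dx = dout)
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function() list(t = 0L, m = list(), v = list())

# params/grads: named flat lists of numeric arrays with matching names.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- if (is.null(state$m[[nm]])) g * 0 else state$m[[nm]]
    v <- if (is.null(state$v[[nm]])) g * 0 else state$v[[nm]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    state$m[[nm]] <- m
    state$v[[nm]] <- v
  }
  list(params = params, state = state)
}
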