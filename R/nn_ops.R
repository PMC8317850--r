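# Low-level neural-network primitives on (H, W, C) arrays.
#
# Convolutions use the im2col lowering: a 3x3 same-padded convolution becomes
# one matrix product between an (H*W) x (9*C_in) patch matrix and a
# (9*C_in) x C_out weight matrix, so all heavy lifting goes through BLAS.
# All functions are internal; the user-facing surface is in unet.R.

# Lower a (H, W, C) array to the (H*W) x (9*C) patch matrix of a 3x3
# convolution with zero padding 1. Patch columns are ordered offset-major:
# for each of the 9 kernel offsets, C contiguous channel columns.
im2col3 <- function(x) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]; ch <- d[3L]
  pad <- array(0, c(h + 2L, w + 2L, ch))
  pad[2:(h + 1L), 2:(w + 1L), ] <- x
  cols <- matrix(0, h * w, 9L * ch)
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      cols[, (k * ch + 1L):((k + 1L) * ch)] <-
        matrix(pad[di + seq_len(h), dj + seq_len(w), , drop = FALSE], h * w, ch)
      k <- k + 1L
    }
  }
  cols
}

# Adjoint of im2col3: scatter patch-matrix gradients back to input pixels.
col2im3 <- function(dcols, h, w, ch) {
  pad <- array(0, c(h + 2L, w + 2L, ch))
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      blk <- array(dcols[, (k * ch + 1L):((k + 1L) * ch)], c(h, w, ch))
      pad[di + seq_len(h), dj + seq_len(w), ] <-
        pad[di + seq_len(h), dj + seq_len(w), , drop = FALSE] + blk
      k <- k + 1L
    }
  }
  pad[2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

# 3x3 same convolution. W is (9*C_in) x C_out, b length C_out.
conv3_forward <- function(x, W, b) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- cols %*% W
  y <- sweep(y, 2L, b, `+`)
  list(out = array(y, c(d[1L], d[2L], ncol(W))), cols = cols)
}

conv3_backward <- function(dout, cols, W, h, w, ch_in) {
  dy <- matrix(dout, h * w, ncol(W))
  list(
    dW = crossprod(cols, dy),
    db = colSums(dy),
    dx = col2im3(dy %*% t(W), h, w, ch_in)
  )
}

relu_forward <- function(x) pmax(x, 0)

relu_backward <- function(dout, x) dout * (x > 0)

# 2x2 max pooling with stride 2. Returns the pooled array and the argmax
# index (1..4 over the block sub-lattices) needed for the backward pass.
maxpool2_forward <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1L], 2L); jo <- seq(1L, d[2L], 2L)
  a <- x[io, jo, , drop = FALSE]
  b <- x[io + 1L, jo, , drop = FALSE]
  cc <- x[io, jo + 1L, , drop = FALSE]
  dd <- x[io + 1L, jo + 1L, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  # first-match tie break, fixed order (top-left, bottom-left, top-right, bottom-right)
  arg <- array(1L, dim(out))
  arg[b  == out & a  < out] <- 2L
  arg[cc == out & a  < out & b  < out] <- 3L
  arg[dd == out & a  < out & b  < out & cc < out] <- 4L
  list(out = out, arg = arg)
}

maxpool2_backward <- function(dout, arg, h, w, ch) {
  dx <- array(0, c(h, w, ch))
  io <- seq(1L, h, 2L); jo <- seq(1L, w, 2L)
  dx[io, jo, ]           <- dout * (arg == 1L)
  dx[io + 1L, jo, ]      <- dout * (arg == 2L)
  dx[io, jo + 1L, ]      <- dout * (arg == 3L)
  dx[io + 1L, jo + 1L, ] <- dout * (arg == 4L)
  dx
}

# Nearest-neighbour 2x upsampling.
upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , drop = FALSE]
}

upsample2_backward <- function(dout) {
  d <- dim(dout)
  io <- seq(1L, d[1L], 2L); jo <- seq(1L, d[2L], 2L)
  dout[io, jo, , drop = FALSE] + dout[io + 1L, jo, , drop = FALSE] +
    dout[io, jo + 1L, , drop = FALSE] + dout[io + 1L, jo + 1L, , drop = FALSE]
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Per-channel sigmoid + binary cross-entropy, averaged over pixels and
# channels, with an optional per-channel positive-class weight to counter
# the strong foreground/background imbalance of small-structure
# segmentation. Returns the scalar loss and the gradient w.r.t. the logits.
bce_logits <- function(z, target, pos_weight = NULL) {
  p <- sigmoid(z)
  eps <- 1e-12
  n <- length(z)
  w <- 1
  if (!is.null(pos_weight) && any(pos_weight != 1)) {
    d <- dim(z)
    w <- array(rep(pos_weight, each = d[1L] * d[2L]), d)
  }
  loss <- -sum(w * target * log(p + eps) + (1 - target) * log(1 - p + eps)) / n
  dz <- (p * (1 + (w - 1) * target) - w * target) / n
  list(loss = loss, dz = dz)
}
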