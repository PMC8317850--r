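#' U-Net configuration
#'
#' Describes a compact encoder--decoder segmentation network: a contracting
#' path of double 3x3 convolution blocks separated by 2x2 maximum pooling, a
#' bottleneck block, and an expanding path of nearest-neighbour upsampling
#' steps each followed by concatenation with the symmetric encoder feature
#' map (the crossover/skip connection) and another double convolution. The
#' output head is a 1x1 convolution with two independent sigmoid channels,
#' one for the stone and one for the kidney, since a stone lies inside the
#' kidney and the two classes are not mutually exclusive.
#'
#' @param depth Number of pooling stages (>= 2). The bottleneck feature map
#'   is `input_size / 2^depth` pixels on a side.
#' @param base_channels Feature channels of the first encoder block; each
#'   deeper block doubles them.
#' @param input_size Side length in pixels of the (square) network input;
#'   must be divisible by `2^depth`.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 3L, base_channels = 8L, input_size = 64L) {
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  input_size <- as.integer(input_size)
  if (depth < 2L) stop("depth must be >= 2")
  if (base_channels < 1L) stop("base_channels must be positive")
  if (input_size %% (2L^depth) != 0L)
    stop("input_size must be divisible by 2^depth")
  structure(
    list(depth = depth, base_channels = base_channels,
         in_channels = 1L, out_channels = 2L, input_size = input_size),
    class = "unet_config"
  )
}

# He-normal initial weights for one 3x3 conv layer.
.init_conv <- function(ch_in, ch_out) {
  list(W = matrix(stats::rnorm(9L * ch_in * ch_out, sd = sqrt(2 / (9 * ch_in))),
                  9L * ch_in, ch_out),
       b = rep(0, ch_out))
}

# Channel bookkeeping shared by init / forward / backward.
.unet_channels <- function(cfg) {
  d <- cfg$depth; base <- cfg$base_channels
  enc <- base * 2L^(seq_len(d) - 1L)     # encoder block outputs, level 1..d
  list(enc = enc, bott = base * 2L^d)
}

#' Build a U-Net model
#'
#' Allocates and initialises all convolution weights (He initialisation,
#' biases at zero).
#'
#' @param config A [unet_config()].
#' @param seed Integer seed controlling weight initialisation.
#' @return An object of class `unet_model` holding the parameter list and
#'   the configuration.
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  ch <- .unet_channels(config)
  d <- config$depth
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    prev <- config$in_channels
    for (i in seq_len(d)) {
      p[[paste0("enc", i, "_c1")]] <- .init_conv(prev, ch$enc[i])
      p[[paste0("enc", i, "_c2")]] <- .init_conv(ch$enc[i], ch$enc[i])
      prev <- ch$enc[i]
    }
    p$bott_c1 <- .init_conv(prev, ch$bott)
    p$bott_c2 <- .init_conv(ch$bott, ch$bott)
    above <- ch$bott
    for (i in rev(seq_len(d))) {
      p[[paste0("dec", i, "_c1")]] <- .init_conv(above + ch$enc[i], ch$enc[i])
      p[[paste0("dec", i, "_c2")]] <- .init_conv(ch$enc[i], ch$enc[i])
      above <- ch$enc[i]
    }
    # 1x1 output head stored as a (C_in x C_out) matrix
    p$head <- list(W = matrix(stats::rnorm(ch$enc[1L] * config$out_channels,
                                           sd = sqrt(2 / ch$enc[1L])),
                              ch$enc[1L], config$out_channels),
                   b = rep(0, config$out_channels))
    p
  })
  structure(list(params = params, config = config), class = "unet_model")
}

#' Number of trainable parameters of a U-Net model
#' @param model A `unet_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  sum(vapply(model$params, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Double conv block forward: conv-relu-conv-relu. Returns output + cache.
.block_forward <- function(x, p1, p2) {
  c1 <- conv3_forward(x, p1$W, p1$b)
  a1 <- relu_forward(c1$out)
  c2 <- conv3_forward(a1, p2$W, p2$b)
  a2 <- relu_forward(c2$out)
  list(out = a2, cols1 = c1$cols, z1 = c1$out, cols2 = c2$cols, z2 = c2$out,
       ch_in = dim(x)[3L])
}

.block_backward <- function(dout, cache, p1, p2) {
  h <- dim(cache$z2)[1L]; w <- dim(cache$z2)[2L]
  dz2 <- relu_backward(dout, cache$z2)
  b2 <- conv3_backward(dz2, cache$cols2, p2$W, h, w, dim(cache$z1)[3L])
  dz1 <- relu_backward(b2$dx, cache$z1)
  b1 <- conv3_backward(dz1, cache$cols1, p1$W, h, w, cache$ch_in)
  list(dx = b1$dx,
       g1 = list(W = b1$dW, b = b1$db),
       g2 = list(W = b2$dW, b = b2$db))
}

# Full forward pass. x is a (H, W, 1) array in [0, 1]. Returns logits
# (H, W, 2) and, when keep_cache, everything the backward pass needs.
unet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params; d <- model$config$depth
  caches <- list(); skips <- list()
  cur <- x
  for (i in seq_len(d)) {
    blk <- .block_forward(cur, p[[paste0("enc", i, "_c1")]], p[[paste0("enc", i, "_c2")]])
    skips[[i]] <- blk$out
    mp <- maxpool2_forward(blk$out)
    if (keep_cache) caches[[paste0("enc", i)]] <- list(blk = blk, arg = mp$arg,
                                                       h = dim(blk$out)[1L],
                                                       w = dim(blk$out)[2L])
    cur <- mp$out
  }
  blk <- .block_forward(cur, p$bott_c1, p$bott_c2)
  if (keep_cache) caches$bott <- list(blk = blk)
  cur <- blk$out
  for (i in rev(seq_len(d))) {
    up <- upsample2_forward(cur)
    ch_up <- dim(up)[3L]
    cat_in <- array(c(up, skips[[i]]), c(dim(up)[1L], dim(up)[2L],
                                         ch_up + dim(skips[[i]])[3L]))
    blk <- .block_forward(cat_in, p[[paste0("dec", i, "_c1")]], p[[paste0("dec", i, "_c2")]])
    if (keep_cache) caches[[paste0("dec", i)]] <- list(blk = blk, ch_up = ch_up)
    cur <- blk$out
  }
  hw <- dim(cur)[1L] * dim(cur)[2L]
  logits <- matrix(cur, hw, dim(cur)[3L]) %*% p$head$W
  logits <- sweep(logits, 2L, p$head$b, `+`)
  logits <- array(logits, c(dim(cur)[1L], dim(cur)[2L], model$config$out_channels))
  if (keep_cache) caches$head_in <- cur
  list(logits = logits, caches = if (keep_cache) caches else NULL)
}

# Backward pass; dlogits has the shape of the logits. Returns gradients in
# the same nested structure as model$params.
unet_backward <- function(model, fw, dlogits) {
  p <- model$params; d <- model$config$depth; caches <- fw$caches
  grads <- list()
  hin <- caches$head_in
  hw <- dim(hin)[1L] * dim(hin)[2L]
  dlm <- matrix(dlogits, hw, dim(dlogits)[3L])
  hm <- matrix(hin, hw, dim(hin)[3L])
  grads$head <- list(W = crossprod(hm, dlm), b = colSums(dlm))
  dcur <- array(dlm %*% t(p$head$W), dim(hin))
  for (i in seq_len(d)) {
    cc <- caches[[paste0("dec", i)]]
    bb <- .block_backward(dcur, cc$blk, p[[paste0("dec", i, "_c1")]],
                          p[[paste0("dec", i, "_c2")]])
    grads[[paste0("dec", i, "_c1")]] <- bb$g1
    grads[[paste0("dec", i, "_c2")]] <- bb$g2
    ch_up <- cc$ch_up
    dup <- bb$dx[, , seq_len(ch_up), drop = FALSE]
    dskip <- bb$dx[, , (ch_up + 1L):dim(bb$dx)[3L], drop = FALSE]
    dcur_below <- upsample2_backward(dup)
    # stash skip gradient; encoder backward consumes it
    caches[[paste0("enc", i)]]$dskip <- dskip
    dcur <- dcur_below
  }
  bb <- .block_backward(dcur, caches$bott$blk, p$bott_c1, p$bott_c2)
  grads$bott_c1 <- bb$g1; grads$bott_c2 <- bb$g2
  dcur <- bb$dx
  for (i in rev(seq_len(d))) {
    cc <- caches[[paste0("enc", i)]]
    dpool <- maxpool2_backward(dcur, cc$arg, cc$h, cc$w, dim(cc$blk$out)[3L])
    dtot <- dpool + cc$dskip
    bb <- .block_backward(dtot, cc$blk, p[[paste0("enc", i, "_c1")]],
                          p[[paste0("enc", i, "_c2")]])
    grads[[paste0("enc", i, "_c1")]] <- bb$g1
    grads[[paste0("enc", i, "_c2")]] <- bb$g2
    dcur <- bb$dx
  }
  grads
}

#' Predict stone and kidney masks for one frame
#'
#' Runs the network in inference mode. Frames whose geometry differs from
#' the network input size are resized with bilinear interpolation on the way
#' in; predicted masks are resized back with nearest-neighbour interpolation
#' so they stay binary.
#'
#' @param model A trained `unet_model`.
#' @param image Numeric matrix (grayscale frame); values are rescaled to
#'   `[0, 1]` if they exceed 1.
#' @param threshold Per-pixel sigmoid probability threshold (default 0.5).
#' @return List with `stone_mask` and `kidney_mask`, 0/1 integer matrices of
#'   the input geometry. An empty stone mask is a valid outcome and feeds
#'   the no-detection path downstream.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  stopifnot(inherits(model, "unet_model"), is.matrix(image))
  size <- model$config$input_size
  orig <- dim(image)
  img <- image
  if (max(img) > 1) img <- img / 255
  if (!all(orig == c(size, size)))
    img <- EBImage::resize(img, w = size, h = size)
  x <- array(img, c(size, size, 1L))
  prob <- sigmoid(unet_forward(model, x)$logits)
  out <- lapply(1:2, function(k) {
    m <- (prob[, , k] >= threshold) * 1L
    if (!all(orig == c(size, size)))
      m <- round(EBImage::resize(m, w = orig[1L], h = orig[2L], filter = "none"))
    matrix(as.integer(m), orig[1L], orig[2L])
  })
  list(stone_mask = out[[1L]], kidney_mask = out[[2L]])
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("U-Net: depth %d, base channels %d, input %dx%d, %d parameters\n",
              cfg$depth, cfg$base_channels, cfg$input_size, cfg$input_size,
              n_parameters(x)))
  invisible(x)
}
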