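# Residual U-Net for cutting-loop segmentation.
#
# A compact fully-convolutional encoder/bridge/decoder network with residual
# blocks in place of pooling: each encoder stage downsamples with a stride-2
# convolution inside a residual block, the bridge is a residual block at the
# bottleneck, and each decoder stage upsamples (nearest-neighbour x2),
# concatenates the matching encoder activation and applies another residual
# block. A final 1x1 convolution produces per-pixel logits; sigmoid gives the
# loop probability. Forward/backward passes are written here directly (the
# only heavy primitives, im2col/col2im, are C++); this keeps the model
# dependency-free and byte-reproducible.
#
# Tensor convention: 4-d arrays (N, H, W, C). Weights: each convolution has a
# (kh*kw*cin) x cout matrix with rows ordered offset-major/channel-minor to
# match the C++ unfolding, plus a length-cout bias.

#' Residual U-Net configuration
#'
#' @param input_size Integer `(H, W)`; both must be divisible by `2^depth`.
#' @param base_filters Channels of the stem stage; doubled at each encoder
#'   stage. Default 64; small test models typically use 8.
#' @param depth Number of stride-2 encoder stages.
#' @return A list of class `"resunet_config"`. The bottleneck ("bridge")
#'   width is `base_filters * 2^depth`.
#' @export
resunet_config <- function(input_size = c(64L, 64L), base_filters = 64L, depth = 3L) {
  input_size <- as.integer(input_size)
  base_filters <- as.integer(base_filters)
  depth <- as.integer(depth)
  if (base_filters < 4L) stop("base_filters must be >= 4")
  if (depth < 1L) stop("depth must be >= 1")
  if (any(input_size %% (2L^depth) != 0L))
    stop("input size ", paste(input_size, collapse = "x"),
         " is not divisible by 2^depth = ", 2L^depth)
  structure(list(input_size = input_size, base_filters = base_filters,
                 depth = depth, bridge_filters = base_filters * 2L^depth),
            class = "resunet_config")
}

# Layer table for the fixed topology; each entry describes one convolution.
resunet_layers <- function(config) {
  f <- config$base_filters; depth <- config$depth
  L <- list()
  add <- function(name, kh, kw, cin, cout, stride, pad)
    L[[name]] <<- list(kh = kh, kw = kw, cin = cin, cout = cout,
                       stride = stride, pad = pad)
  add("stem", 3, 3, 3, f, 1, 1)
  for (i in seq_len(depth)) {
    cin <- f * 2L^(i - 1L); cout <- f * 2L^i
    add(sprintf("enc%d.c1", i), 3, 3, cin, cout, 2, 1)
    add(sprintf("enc%d.c2", i), 3, 3, cout, cout, 1, 1)
    add(sprintf("enc%d.sc", i), 1, 1, cin, cout, 2, 0)
  }
  cb <- f * 2L^depth
  add("bridge.c1", 3, 3, cb, cb, 1, 1)
  add("bridge.c2", 3, 3, cb, cb, 1, 1)
  add("bridge.sc", 1, 1, cb, cb, 1, 0)
  for (j in seq_len(depth)) {
    below <- f * 2L^j; skip <- f * 2L^(j - 1L)
    cin <- below + skip; cout <- skip
    add(sprintf("dec%d.c1", j), 3, 3, cin, cout, 1, 1)
    add(sprintf("dec%d.c2", j), 3, 3, cout, cout, 1, 1)
    add(sprintf("dec%d.sc", j), 1, 1, cin, cout, 1, 0)
  }
  add("final", 1, 1, f, 1, 1, 0)
  L
}

#' Build a residual U-Net segmenter
#'
#' Initialises all convolution weights with He-normal draws (seeded, so the
#' same seed always yields the same network) and zero biases.
#'
#' @param config A [resunet_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `"resunet"`.
#' @export
build_resunet <- function(config = resunet_config(), seed = 1L) {
  if (!inherits(config, "resunet_config")) config <- do.call(resunet_config, config)
  layers <- resunet_layers(config)
  params <- with_local_seed(seed, {
    p <- list()
    for (nm in names(layers)) {
      m <- layers[[nm]]
      fan_in <- m$kh * m$kw * m$cin
      p[[paste0(nm, ".W")]] <- matrix(rnorm(fan_in * m$cout, 0, sqrt(2 / fan_in)),
                                      fan_in, m$cout)
      p[[paste0(nm, ".b")]] <- numeric(m$cout)
    }
    p
  })
  structure(list(config = config, layers = layers, params = params,
                 history = numeric(0)), class = "resunet")
}

#' @export
print.resunet <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf("Residual U-Net segmenter: input %dx%d, depth %d, base %d filters (bridge %d), %s parameters\n",
              cfg$input_size[1], cfg$input_size[2], cfg$depth, cfg$base_filters,
              cfg$bridge_filters, format(n_par, big.mark = ",")))
  if (length(x$history))
    cat(sprintf("  trained %d epochs; final loss %.4f\n",
                length(x$history), x$history[length(x$history)]))
  invisible(x)
}

conv_apply <- function(params, layers, nm, X) {
  m <- layers[[nm]]
  d <- dim(X)
  col <- im2col_nhwc(X, m$kh, m$kw, m$stride, m$pad)
  Y <- col %*% params[[paste0(nm, ".W")]]
  b <- params[[paste0(nm, ".b")]]
  if (any(b != 0)) Y <- Y + rep(b, each = nrow(Y))
  ho <- (d[2] + 2L * m$pad - m$kh) %/% m$stride + 1L
  wo <- (d[3] + 2L * m$pad - m$kw) %/% m$stride + 1L
  array(Y, c(d[1], ho, wo, m$cout))
}

# `grads` is an environment so accumulation is in place across the recursion.
conv_grad <- function(params, layers, nm, Xin, dY, grads) {
  m <- layers[[nm]]
  d <- dim(Xin)
  dYmat <- matrix(dY, prod(dim(dY)[1:3]), dim(dY)[4])
  col <- im2col_nhwc(Xin, m$kh, m$kw, m$stride, m$pad)
  wk <- paste0(nm, ".W"); bk <- paste0(nm, ".b")
  gW <- crossprod(col, dYmat)
  gb <- colSums(dYmat)
  grads[[wk]] <- if (is.null(grads[[wk]])) gW else grads[[wk]] + gW
  grads[[bk]] <- if (is.null(grads[[bk]])) gb else grads[[bk]] + gb
  dcol <- dYmat %*% t(params[[wk]])
  col2im_nhwc(dcol, d[1], d[2], d[3], d[4], m$kh, m$kw, m$stride, m$pad)
}

res_block_fwd <- function(params, layers, nm, X) {
  h1pre <- conv_apply(params, layers, paste0(nm, ".c1"), X)
  h1 <- pmax(h1pre, 0)
  h2 <- conv_apply(params, layers, paste0(nm, ".c2"), h1)
  s <- conv_apply(params, layers, paste0(nm, ".sc"), X)
  pre <- h2 + s
  list(out = pmax(pre, 0), cache = list(X = X, h1 = h1, pre = pre))
}

res_block_bwd <- function(params, layers, nm, cache, dY, grads) {
  dpre <- dY * (cache$pre > 0)
  dh1 <- conv_grad(params, layers, paste0(nm, ".c2"), cache$h1, dpre, grads)
  dh1 <- dh1 * (cache$h1 > 0)
  dX <- conv_grad(params, layers, paste0(nm, ".c1"), cache$X, dh1, grads)
  dX + conv_grad(params, layers, paste0(nm, ".sc"), cache$X, dpre, grads)
}

up2 <- function(X) {
  d <- dim(X)
  X[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

up2_bwd <- function(dY) {
  d <- dim(dY)
  ri <- seq(1L, d[2], by = 2L); ci <- seq(1L, d[3], by = 2L)
  dY[, ri, ci, , drop = FALSE] + dY[, ri + 1L, ci, , drop = FALSE] +
    dY[, ri, ci + 1L, , drop = FALSE] + dY[, ri + 1L, ci + 1L, , drop = FALSE]
}

# Forward pass. X: (N, H, W, 3) in [0, 1], H and W divisible by 2^depth.
# Returns per-pixel logits (N, H, W, 1), plus all intermediates when
# want_cache = TRUE (needed for the backward pass).
resunet_forward <- function(model, X, want_cache = FALSE) {
  P <- model$params; L <- model$layers; depth <- model$config$depth
  d <- dim(X)
  if (any(d[2:3] %% (2L^depth) != 0L))
    stop("input spatial size must be divisible by 2^depth")
  cache <- if (want_cache) list(enc = vector("list", depth),
                                dec = vector("list", depth)) else NULL
  a0 <- pmax(conv_apply(P, L, "stem", X), 0)
  if (want_cache) { cache$X <- X; cache$a0 <- a0 }
  skips <- vector("list", depth + 1L)
  skips[[1L]] <- a0
  x <- a0
  for (i in seq_len(depth)) {
    blk <- res_block_fwd(P, L, sprintf("enc%d", i), x)
    x <- blk$out
    skips[[i + 1L]] <- x
    if (want_cache) cache$enc[[i]] <- blk$cache
  }
  blk <- res_block_fwd(P, L, "bridge", x)
  x <- blk$out
  if (want_cache) cache$bridge <- blk$cache
  for (j in rev(seq_len(depth))) {
    xu <- up2(x)
    cat_in <- array(c(xu, skips[[j]]), c(dim(xu)[1:3], dim(xu)[4] + dim(skips[[j]])[4]))
    blk <- res_block_fwd(P, L, sprintf("dec%d", j), cat_in)
    x <- blk$out
    if (want_cache) cache$dec[[j]] <- c(blk$cache, list(c_up = dim(xu)[4]))
  }
  z <- conv_apply(P, L, "final", x)
  if (want_cache) { cache$final_in <- x; list(logits = z, cache = cache) }
  else z
}

# Backward pass: gradients of a scalar loss w.r.t. every parameter, given
# dZ = dLoss/dlogits. Mirrors resunet_forward exactly.
resunet_backward <- function(model, cache, dZ) {
  P <- model$params; L <- model$layers; depth <- model$config$depth
  grads <- new.env(parent = emptyenv())
  dX <- conv_grad(P, L, "final", cache$final_in, dZ, grads)
  dskip <- vector("list", depth)
  for (j in seq_len(depth)) {
    cj <- cache$dec[[j]]
    dcat <- res_block_bwd(P, L, sprintf("dec%d", j), cj, dX, grads)
    cu <- cj$c_up
    dskip[[j]] <- dcat[, , , (cu + 1L):dim(dcat)[4], drop = FALSE]
    dX <- up2_bwd(dcat[, , , seq_len(cu), drop = FALSE])
  }
  dX <- res_block_bwd(P, L, "bridge", cache$bridge, dX, grads)
  for (i in rev(seq_len(depth))) {
    dX <- res_block_bwd(P, L, sprintf("enc%d", i), cache$enc[[i]], dX, grads)
    if (i <= depth && !is.null(dskip[[i]])) dX <- dX + dskip[[i]]
  }
  # dX is now the gradient w.r.t. the stem activation a0
  d_stem <- dX * (cache$a0 > 0)
  conv_grad(P, L, "stem", cache$X, d_stem, grads)
  out <- as.list(grads)
  out[names(model$params)]
}
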