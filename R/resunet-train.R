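# Training and applying the loop segmenter.

#' Segmenter training configuration
#'
#' @param epochs Number of passes over the training set (`0` returns the
#'   model untrained with an empty loss history).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param loss One of `"bce"`, `"dice"`, `"bce+dice"` (their sum; default --
#'   binary cross-entropy is well-conditioned early on, the Dice term drives
#'   overlap for small foreground objects).
#' @param seed Seed controlling shuffling (and weight init when the model is
#'   built internally).
#' @param mask_threshold Probability cutoff used when binarising predictions.
#' @return A list of class `"seg_train_config"`.
#' @export
seg_train_config <- function(epochs = 20L, batch_size = 8L, learning_rate = 1e-3,
                             loss = c("bce+dice", "bce", "dice"), seed = 1L,
                             mask_threshold = 0.5) {
  loss <- match.arg(loss)
  if (epochs < 0 || batch_size < 1 || learning_rate <= 0)
    stop("epochs must be >= 0, batch_size >= 1, learning_rate > 0")
  if (mask_threshold <= 0 || mask_threshold >= 1)
    stop("mask_threshold must be in (0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed), mask_threshold = mask_threshold),
            class = "seg_train_config")
}

seg_loss_grad <- function(z, g, loss_name) {
  n <- length(z)
  p <- 1 / (1 + exp(-z))
  loss <- 0; dz <- 0
  if (loss_name %in% c("bce", "bce+dice")) {
    loss <- loss + mean(pmax(z, 0) - z * g + log1p(exp(-abs(z))))
    dz <- dz + (p - g) / n
  }
  if (loss_name %in% c("dice", "bce+dice")) {
    eps <- 1e-6
    S <- sum(p * g); A <- sum(p); B <- sum(g)
    loss <- loss + 1 - (2 * S + eps) / (A + B + eps)
    dd_dp <- (2 * g * (A + B + eps) - (2 * S + eps)) / (A + B + eps)^2
    dz <- dz - dd_dp * p * (1 - p)
  }
  list(loss = loss, dz = dz)
}

#' Train the cutting-loop segmenter
#'
#' Optimises the network with Adam on binary cross-entropy and/or Dice loss.
#' Frames are scaled to `[0, 1]` and, together with their masks, resized to
#' the model's input size if needed (bilinear for frames, nearest-neighbour
#' for masks). Fully deterministic for a fixed seed.
#'
#' @param images List of `H x W x 3` frames with values in `[0, 255]`.
#' @param masks List of logical matrices (ground-truth loop masks), shapes
#'   matching the corresponding frames.
#' @param cfg A [seg_train_config()].
#' @param model A [build_resunet()] model to start from; if `NULL` one is
#'   built with default configuration sized to the first frame.
#' @return The trained `"resunet"` model; `$history` holds the mean training
#'   loss per epoch (length `cfg$epochs`).
#' @export
train_segmenter <- function(images, masks, cfg = seg_train_config(), model = NULL) {
  if (length(images) == 0L) stop("need at least one (image, mask) pair")
  if (length(images) != length(masks)) stop("images and masks differ in length")
  for (i in seq_along(images)) {
    di <- dim(images[[i]])[1:2]; dm <- dim(masks[[i]])
    if (any(di != dm))
      stop("image/mask shape mismatch at index ", i, " (",
           paste(di, collapse = "x"), " vs ", paste(dm, collapse = "x"), ")")
  }
  if (is.null(model)) {
    sz <- dim(images[[1]])[1:2]
    model <- build_resunet(resunet_config(input_size = sz), seed = cfg$seed)
  }
  h <- model$config$input_size[1]; w <- model$config$input_size[2]
  n <- length(images)
  X <- array(0, c(n, h, w, 3))
  G <- array(0, c(n, h, w, 1))
  for (i in seq_len(n)) {
    fr <- images[[i]] / 255
    if (any(dim(fr)[1:2] != c(h, w))) fr <- resize_bilinear_frame(fr, h, w)
    mk <- masks[[i]]
    if (any(dim(mk) != c(h, w))) mk <- resize_nearest_mat(mk, h, w)
    X[i, , , ] <- fr
    G[i, , , 1] <- mk * 1.0
  }
  if (cfg$epochs == 0L) { model$history <- numeric(0); return(model) }

  P <- model$params
  mom <- lapply(P, function(p) p * 0)
  vel <- lapply(P, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  history <- numeric(cfg$epochs)
  with_local_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        model$params <- P
        fw <- resunet_forward(model, X[bi, , , , drop = FALSE], want_cache = TRUE)
        lg <- seg_loss_grad(fw$logits, G[bi, , , , drop = FALSE], cfg$loss)
        gr <- resunet_backward(model, fw$cache,
                               array(lg$dz, dim(fw$logits)))
        t <- t + 1
        for (nm in names(P)) {
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gr[[nm]]
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gr[[nm]]^2
          mhat <- mom[[nm]] / (1 - b1^t)
          vhat <- vel[[nm]] / (1 - b2^t)
          P[[nm]] <- P[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + lg$loss * length(bi)
      }
      history[ep] <- ep_loss / n
    }
  })
  model$params <- P
  model$history <- c(model$history, history)
  model
}

#' Predict a cutting-loop mask for one frame
#'
#' The frame is scaled to `[0, 1]`, resized (bilinear) to the model's input
#' size, passed through the network, thresholded with a strict `>` (so an
#' all-zero-logit model yields an empty mask at the default 0.5), and the
#' binary map is returned at the frame's original resolution via
#' nearest-neighbour upsampling.
#'
#' @param model A trained `"resunet"`.
#' @param frame `H x W x 3` array in `[0, 255]`.
#' @param threshold Probability cutoff in `(0, 1)`; `0` is accepted and
#'   yields a full mask for any model with positive outputs.
#' @return A logical `H x W` matrix.
#' @export
predict_loop_mask <- function(model, frame, threshold = 0.5) {
  stopifnot_frame(frame)
  h0 <- dim(frame)[1]; w0 <- dim(frame)[2]
  h <- model$config$input_size[1]; w <- model$config$input_size[2]
  fr <- frame / 255
  if (h0 != h || w0 != w) fr <- resize_bilinear_frame(fr, h, w)
  X <- array(fr, c(1, h, w, 3))
  z <- resunet_forward(model, X)
  p <- 1 / (1 + exp(-z[1, , , 1]))
  small <- matrix(p > threshold, h, w)
  resize_nearest_mat(small, h0, w0)
}

#' Save / load a segmenter checkpoint
#'
#' Serialisation round-trips bit-exactly: the reloaded model reproduces
#' predictions identically.
#'
#' @param model A `"resunet"` model.
#' @param path Checkpoint file path.
#' @return `load_resunet()` returns the model; `save_resunet()` returns
#'   `path` invisibly.
#' @export
save_resunet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_resunet
#' @export
load_resunet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "resunet")) stop("not a resunet checkpoint: ", path)
  model
}
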