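# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's stream after.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-item seed derived from a master seed; stays inside the
# 32-bit integer range so set.seed() accepts it.
derive_seed <- function(master, index) {
  as.integer((abs(as.numeric(master)) * 100003 + as.numeric(index) * 7919 + 1) %% 2147483647)
}

stopifnot_frame <- function(frame) {
  if (!is.array(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("frame must be an H x W x 3 array", call. = FALSE)
  if (min(frame) < 0 || max(frame) > 255)
    stop("frame channel values must lie in [0, 255]", call. = FALSE)
  invisible(frame)
}

stopifnot_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("%s must be a logical matrix", name), call. = FALSE)
  invisible(mask)
}

check_same_shape <- function(a, b, what = "masks") {
  da <- dim(a); db <- dim(b)
  if (length(da) != length(db) || any(da != db))
    stop(sprintf("%s must have identical shapes (%s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

# Bilinear resize of a single H x W matrix (values interpolated).
resize_bilinear_mat <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  # map output pixel centers into input pixel-center coordinates
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(ys - y0, 0), 1)
  wx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  wy_m <- matrix(wy, out_h, out_w)
  wx_m <- matrix(wx, out_h, out_w, byrow = TRUE)
  top <- a * (1 - wx_m) + b * wx_m
  bot <- c_ * (1 - wx_m) + d * wx_m
  top * (1 - wy_m) + bot * wy_m
}

resize_bilinear_frame <- function(frame, out_h, out_w) {
  out <- array(0, c(out_h, out_w, dim(frame)[3]))
  for (c in seq_len(dim(frame)[3]))
    out[, , c] <- resize_bilinear_mat(frame[, , c], out_h, out_w)
  out
}

# Nearest-neighbour resize for masks/labels (no interpolation of classes).
resize_nearest_mat <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  yi <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * h / out_h), 1), h)
  xi <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * w / out_w), 1), w)
  m[yi, xi, drop = FALSE]
}
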