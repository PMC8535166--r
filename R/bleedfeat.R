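# Bleeding-region extraction in YCbCr space and per-frame/per-video features.

#' Convert an RGB frame to YCbCr
#'
#' BT.601 full-range transform (the common default of imaging libraries):
#' `Y = 0.299 R + 0.587 G + 0.114 B`,
#' `Cb = 128 - 0.168736 R - 0.331264 G + 0.5 B`,
#' `Cr = 128 + 0.5 R - 0.418688 G - 0.081312 B`, all clipped to `[0, 255]`.
#' The Cr channel isolates redness, which is what the blood rule keys on.
#'
#' @param frame `H x W x 3` array in `[0, 255]`.
#' @return A list with matrices `Y`, `Cb`, `Cr`.
#' @export
rgb_to_ycbcr <- function(frame) {
  stopifnot_frame(frame)
  R <- frame[, , 1]; G <- frame[, , 2]; B <- frame[, , 3]
  clip <- function(m) pmin(pmax(m, 0), 255)
  list(Y  = clip(0.299 * R + 0.587 * G + 0.114 * B),
       Cb = clip(128 - 0.168736 * R - 0.331264 * G + 0.5 * B),
       Cr = clip(128 + 0.5 * R - 0.418688 * G - 0.081312 * B))
}

#' Red (blood) chroma thresholds
#'
#' A pixel counts as blood-red when `Cr >= cr_min` and `Cb <= cb_max`. The
#' defaults (150 / 130 on the 8-bit scale) let pure red pass while neutral
#' gray and white glare fail.
#'
#' @param cr_min Minimum Cr.
#' @param cb_max Maximum Cb.
#' @return A list of class `"red_thresholds"`.
#' @export
red_thresholds <- function(cr_min = 150, cb_max = 130) {
  if (cr_min < 0 || cr_min > 255 || cb_max < 0 || cb_max > 255)
    stop("thresholds must lie in [0, 255]")
  structure(list(cr_min = cr_min, cb_max = cb_max), class = "red_thresholds")
}

#' Extract the red (candidate-blood) mask of a frame
#'
#' @param ycc A YCbCr frame from [rgb_to_ycbcr()].
#' @param th Thresholds from [red_thresholds()].
#' @return A logical matrix, `TRUE` where the pixel is blood-red.
#' @export
extract_red_mask <- function(ycc, th = red_thresholds()) {
  ycc$Cr >= th$cr_min & ycc$Cb <= th$cb_max
}

#' Remove the cutting loop from a red mask
#'
#' The loop's red glow would otherwise be counted as blood; pixels under the
#' predicted (or ground-truth) loop mask are cleared.
#'
#' @param red_mask,loop_mask Logical matrices of identical shape.
#' @return `red_mask & !loop_mask`.
#' @export
eliminate_loop <- function(red_mask, loop_mask) {
  stopifnot_mask(red_mask, "red_mask"); stopifnot_mask(loop_mask, "loop_mask")
  check_same_shape(red_mask, loop_mask)
  red_mask & !loop_mask
}

#' Count bleeding regions in a binary mask
#'
#' Connected components of foreground pixels, with components below
#' `min_area` pixels discarded (speckle suppression).
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default) neighbourhood.
#' @param min_area Minimum component size in pixels kept (0 keeps all).
#' @return Integer count of surviving components.
#' @export
count_bleeding_regions <- function(mask, connectivity = 8L, min_area = 1L) {
  stopifnot_mask(mask)
  if (!sum(mask)) return(0L)
  lab <- label_components_cpp(mask, as.integer(connectivity))
  areas <- tabulate(lab[lab > 0L])
  sum(areas >= max(min_area, 1L))
}

#' Bleeding ratio of a frame
#'
#' Fraction of valid (non-occluded) pixels classified as blood. The
#' denominator excludes loop pixels: the loop is eliminated, so it is
#' neither blood nor visible surgical field, and a large loop should not
#' dilute the ratio.
#'
#' @param bleeding_mask Logical matrix of blood pixels.
#' @param valid_mask Logical matrix of valid pixels (typically `!loop_mask`);
#'   must contain at least one `TRUE` pixel.
#' @return A number in `[0, 1]`.
#' @export
bleeding_ratio <- function(bleeding_mask, valid_mask) {
  stopifnot_mask(bleeding_mask, "bleeding_mask"); stopifnot_mask(valid_mask, "valid_mask")
  check_same_shape(bleeding_mask, valid_mask)
  nv <- sum(valid_mask)
  if (nv == 0L) stop("frame fully occluded")
  sum(bleeding_mask & valid_mask) / nv
}

# min_area is calibrated at 256x256 and scaled with frame area so the same
# physical speckle size is suppressed at any resolution.
scale_min_area <- function(min_area, H, W) {
  max(1L, as.integer(round(min_area * (H * W) / (256 * 256))))
}

#' Per-frame bleeding features
#'
#' Runs the full frame chain: YCbCr conversion, red-mask extraction, loop
#' elimination, bleeding ratio over non-loop pixels, and region counting
#' with a resolution-scaled minimum area (`min_area` is specified at
#' 256x256 and scaled by `H*W / 256^2`).
#'
#' @param frame `H x W x 3` array in `[0, 255]`.
#' @param loop_mask Logical loop mask, or `NULL` for no occlusion.
#' @param th [red_thresholds()].
#' @param connectivity 4 or 8.
#' @param min_area Minimum region area at 256x256 reference resolution.
#' @return A list with `bleeding_ratio` and `region_count`.
#' @export
frame_features <- function(frame, loop_mask = NULL, th = red_thresholds(),
                           connectivity = 8L, min_area = 20L) {
  stopifnot_frame(frame)
  H <- dim(frame)[1]; W <- dim(frame)[2]
  if (is.null(loop_mask)) loop_mask <- matrix(FALSE, H, W)
  red <- extract_red_mask(rgb_to_ycbcr(frame), th)
  bleeding <- eliminate_loop(red, loop_mask)
  list(bleeding_ratio = bleeding_ratio(bleeding, !loop_mask),
       region_count = count_bleeding_regions(bleeding, connectivity,
                                             scale_min_area(min_area, H, W)))
}

#' Per-video bleeding features
#'
#' Arithmetic mean over frames of the per-frame bleeding ratio and region
#' count; this 2-d point is what the rank classifiers consume.
#'
#' @param frames Non-empty list of frames.
#' @param loop_masks List of loop masks matching `frames` (or `NULL`).
#' @inheritParams frame_features
#' @return A list with `mean_bleeding_ratio` and `mean_region_count`.
#' @export
video_features <- function(frames, loop_masks = NULL, th = red_thresholds(),
                           connectivity = 8L, min_area = 20L) {
  if (length(frames) == 0L) stop("empty frame list")
  if (!is.null(loop_masks) && length(loop_masks) != length(frames))
    stop("frames and loop_masks differ in length")
  ff <- lapply(seq_along(frames), function(i)
    frame_features(frames[[i]],
                   if (is.null(loop_masks)) NULL else loop_masks[[i]],
                   th, connectivity, min_area))
  list(mean_bleeding_ratio = mean(vapply(ff, `[[`, 0, "bleeding_ratio")),
       mean_region_count = mean(vapply(ff, `[[`, 0, "region_count")))
}

#' Write per-frame debug panels
#'
#' Visual audit trail of the frame chain, written as four PNGs:
#' `<prefix>_input.png` the frame, `<prefix>_red.png` the raw red mask,
#' `<prefix>_noloop.png` the frame with loop pixels blacked out, and
#' `<prefix>_bleeding.png` the final bleeding mask after loop elimination.
#'
#' @inheritParams frame_features
#' @param prefix Output path prefix (directories must exist).
#' @return Character vector of the four paths written, invisibly.
#' @export
write_debug_panels <- function(frame, loop_mask = NULL, prefix,
                               th = red_thresholds()) {
  stopifnot_frame(frame)
  H <- dim(frame)[1]; W <- dim(frame)[2]
  if (is.null(loop_mask)) loop_mask <- matrix(FALSE, H, W)
  red <- extract_red_mask(rgb_to_ycbcr(frame), th)
  bleeding <- eliminate_loop(red, loop_mask)
  noloop <- frame
  for (c in 1:3) { ch <- noloop[, , c]; ch[loop_mask] <- 0; noloop[, , c] <- ch }
  paths <- paste0(prefix, c("_input.png", "_red.png", "_noloop.png", "_bleeding.png"))
  write_frame(frame, paths[1])
  write_mask(red, paths[2])
  write_frame(noloop, paths[3])
  write_mask(bleeding, paths[4])
  invisible(paths)
}

#' Min-max feature normalization
#'
#' Fits per-column minimum and maximum on the training features only and
#' maps both sets into `[0, 1]`; applied values outside the training range
#' are clipped. A constant training column maps to 0.
#'
#' @param train Numeric matrix (rows = videos, columns = features);
#'   non-empty.
#' @param apply_to Optional matrix to transform with the training bounds.
#' @return A list with `train` (scaled), `applied` (scaled `apply_to` or
#'   `NULL`), and `bounds` (2 x ncol matrix of min/max).
#' @export
normalize_features <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("training features must be non-empty")
  lo <- apply(train, 2, min); hi <- apply(train, 2, max)
  scale1 <- function(m) {
    out <- m
    for (j in seq_len(ncol(m))) {
      rng <- hi[j] - lo[j]
      out[, j] <- if (rng == 0) 0 else pmin(pmax((m[, j] - lo[j]) / rng, 0), 1)
    }
    out
  }
  list(train = scale1(train),
       applied = if (!is.null(apply_to)) scale1(as.matrix(apply_to)) else NULL,
       bounds = rbind(min = lo, max = hi))
}
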