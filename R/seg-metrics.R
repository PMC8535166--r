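# Segmentation overlap metrics.

#' Intersection-over-union and Dice coefficient of two binary masks
#'
#' `iou()` is the ratio of the overlap to the union of predicted and
#' ground-truth masks; `dice()` is twice the overlap divided by the sum of
#' the two areas. Both range over `[0, 1]`: 0 means no overlap, 1 identical
#' masks, and the pair always satisfies `dice = 2*iou / (1 + iou)`. When both
#' masks are empty the agreement is perfect and both metrics are defined as
#' 1.
#'
#' @param predicted,ground_truth Logical matrices of identical shape.
#' @return A number in `[0, 1]`.
#' @export
iou <- function(predicted, ground_truth) {
  stopifnot_mask(predicted, "predicted"); stopifnot_mask(ground_truth, "ground_truth")
  check_same_shape(predicted, ground_truth)
  u <- sum(predicted | ground_truth)
  if (u == 0L) return(1.0)
  sum(predicted & ground_truth) / u
}

#' @rdname iou
#' @export
dice <- function(predicted, ground_truth) {
  stopifnot_mask(predicted, "predicted"); stopifnot_mask(ground_truth, "ground_truth")
  check_same_shape(predicted, ground_truth)
  s <- sum(predicted) + sum(ground_truth)
  if (s == 0L) return(1.0)
  2 * sum(predicted & ground_truth) / s
}
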