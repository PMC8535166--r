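# Independent brute-force oracles used across the suite. These are written
# as literally as possible (per-pixel loops, exhaustive scans) so they stay
# independent of the vectorised/compiled implementation paths they check.

# Pixel-by-pixel IoU / Dice.
oracle_iou <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j] && b[i, j]) inter <- inter + 1
    if (a[i, j] || b[i, j]) uni <- uni + 1
  }
  if (uni == 0) 1.0 else inter / uni
}

oracle_dice <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j] && b[i, j]) inter <- inter + 1
    if (a[i, j]) sa <- sa + 1
    if (b[i, j]) sb <- sb + 1
  }
  if (sa + sb == 0) 1.0 else 2 * inter / (sa + sb)
}

# Recursive flood fill region counter.
oracle_count_regions <- function(mask, connectivity, min_area = 1L) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  count <- 0L
  for (i0 in seq_len(H)) for (j0 in seq_len(W)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    area <- 0L
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      area <- area + 1L
      for (o in offs) {
        ii <- p[1] + o[1]; jj <- p[2] + o[2]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
    if (area >= min_area) count <- count + 1L
  }
  count
}

# Exhaustive-scan KNN: all pairwise distances, majority with the same
# documented tie-break (smaller mean distance, then lower score).
oracle_knn <- function(X, y, q, k) {
  d <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) d[i] <- sqrt(sum((X[i, ] - q)^2))
  nn <- order(d)[seq_len(k)]
  lab <- y[nn]
  counts <- sapply(sort(unique(lab)), function(l) sum(lab == l))
  names(counts) <- sort(unique(lab))
  cand <- as.integer(names(counts)[counts == max(counts)])
  if (length(cand) > 1) {
    md <- sapply(cand, function(l) mean(d[nn][lab == l]))
    cand <- cand[md == min(md)]
  }
  min(cand)
}

# Direct per-item one-vs-rest tallies for accuracy/precision/recall.
oracle_metrics <- function(actual, predicted, average = "macro") {
  acc <- mean(actual == predicted)
  precs <- c(); recs <- c()
  tps <- fps <- fns <- 0
  for (cl in 0:3) {
    tp <- sum(actual == cl & predicted == cl)
    fp <- sum(actual != cl & predicted == cl)
    fn <- sum(actual == cl & predicted != cl)
    tps <- tps + tp; fps <- fps + fp; fns <- fns + fn
    if (tp + fp > 0) precs <- c(precs, tp / (tp + fp))
    if (tp + fn > 0) recs <- c(recs, tp / (tp + fn))
  }
  if (average == "micro")
    list(accuracy = acc, precision = tps / (tps + fps), recall = tps / (tps + fns))
  else
    list(accuracy = acc, precision = mean(precs), recall = mean(recs))
}

random_mask <- function(h, w, p = 0.4) matrix(runif(h * w) < p, h, w)
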