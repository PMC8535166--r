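# Consensus labeling, dataset splitting, and the four rank classifiers.
#
# The bleeding level is an ordinal score 0-3 (0 excellent, 1 acceptable,
# 2 slightly bad, 3 bad) but, as is usual for this kind of small 2-d feature
# problem, the classifiers treat it as nominal; ordinality enters only
# through the adjacent-level-tolerant evaluation.

#' Ordinal rank labels
#'
#' @return Named character vector mapping the scores 0-3 to their clinical
#'   meaning.
#' @export
rank_labels <- function() {
  c(`0` = "excellent", `1` = "acceptable", `2` = "slightly bad", `3` = "bad")
}

#' Consensus label from three evaluator scores
#'
#' All three equal: that score. Exactly two equal: the majority score. All
#' distinct: no consensus -- the clip needs re-evaluation, signalled by
#' `NA`.
#'
#' @param scores Integer vector of length 3, each in `[0, 3]`.
#' @return The consensus score (integer), or `NA` when all three disagree.
#' @export
consensus_label <- function(scores) {
  if (length(scores) != 3L) stop("need exactly three evaluator scores")
  if (any(scores < 0 | scores > 3) || any(scores != round(scores)))
    stop("evaluator scores must be integers in [0, 3]")
  tab <- table(scores)
  if (max(tab) >= 2L) as.integer(names(tab)[which.max(tab)]) else NA_integer_
}

#' Stratified train/validation split
#'
#' Holds out `val_fraction` of the ids, stratified by label where possible
#' (per-class held-out counts differ by at most one for balanced classes).
#' Deterministic for a fixed seed; the two sets partition the input.
#'
#' @param ids Character vector of video ids.
#' @param labels Integer labels aligned with `ids`.
#' @param val_fraction Fraction held out, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `val`.
#' @export
split_train_val <- function(ids, labels, val_fraction = 0.10, seed = 1L) {
  if (length(ids) != length(labels)) stop("ids and labels differ in length")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  with_local_seed(seed, {
    val <- character(0)
    for (lv in sort(unique(labels))) {
      members <- ids[labels == lv]
      n_val <- round(val_fraction * length(members))
      if (n_val > 0) val <- c(val, sample(members, n_val))
    }
    list(train = setdiff(ids, val), val = val)
  })
}

#' Classifier specification
#'
#' @param kind One of `"knn"`, `"naive_bayes"`, `"random_forest"`, `"svm"`.
#' @param knn_k Odd positive neighbour count for KNN.
#' @param svm_C Soft-margin regularization parameter C.
#' @param svm_kernel `"rbf"` or `"linear"`.
#' @param rf_trees Number of random-forest trees.
#' @param seed Seed for the stochastic learners (random forest).
#' @return A list of class `"classifier_spec"`.
#' @export
classifier_spec <- function(kind = c("knn", "naive_bayes", "random_forest", "svm"),
                            knn_k = 5L, svm_C = 1.0, svm_kernel = c("rbf", "linear"),
                            rf_trees = 100L, seed = 1L) {
  kind <- match.arg(kind)
  svm_kernel <- match.arg(svm_kernel)
  if (knn_k < 1L || knn_k %% 2L == 0L) stop("knn_k must be an odd positive integer")
  if (svm_C <= 0) stop("svm_C must be positive")
  if (rf_trees < 1L) stop("rf_trees must be positive")
  structure(list(kind = kind, knn_k = as.integer(knn_k), svm_C = svm_C,
                 svm_kernel = svm_kernel, rf_trees = as.integer(rf_trees),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

as_feature_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features) && !is.matrix(features)) {
    m <- t(vapply(features, function(f)
      c(f$mean_bleeding_ratio, f$mean_region_count), numeric(2)))
  } else m <- as.matrix(features)
  colnames(m) <- c("bleeding_ratio", "region_count")
  m
}

#' Fit a bleeding-rank classifier
#'
#' Features are min-max normalized internally (bounds fitted on the training
#' set and stored with the model, so prediction normalizes consistently).
#' The four kinds are: KNN with Euclidean distance and a fixed tie-break
#' (majority, then smaller mean distance, then lower score); Gaussian naive
#' Bayes; random forest (majority vote of trees; seeded); and a soft-margin
#' SVM with one-vs-one multi-class handling.
#'
#' @param spec A [classifier_spec()].
#' @param features Matrix of raw video features (rows = videos, columns =
#'   bleeding ratio and region count), or a list of [video_features()]
#'   results.
#' @param labels Integer ranks in `[0, 3]`, one per row; at least two
#'   distinct classes are required.
#' @return An object of class `"bleed_classifier"` supporting [predict()].
#' @export
train_classifier <- function(spec, features, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as_feature_matrix(features)
  labels <- as.integer(labels)
  if (nrow(X) != length(labels)) stop("features and labels differ in length")
  if (any(labels < 0 | labels > 3)) stop("labels must be in [0, 3]")
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class; need at least two")
  if (spec$kind == "knn" && spec$knn_k > nrow(X))
    stop("knn_k exceeds the training-set size")
  nrm <- normalize_features(X)
  Xs <- nrm$train
  y <- factor(labels, levels = 0:3)
  fit <- switch(spec$kind,
    knn = list(X = Xs, y = labels),
    naive_bayes = e1071::naiveBayes(Xs, y),
    random_forest = with_local_seed(spec$seed,
      randomForest::randomForest(Xs, y, ntree = spec$rf_trees)),
    svm = e1071::svm(Xs, y, scale = FALSE, cost = spec$svm_C,
                     kernel = if (spec$svm_kernel == "rbf") "radial" else "linear")
  )
  structure(list(spec = spec, fit = fit, bounds = nrm$bounds),
            class = "bleed_classifier")
}

#' @export
print.bleed_classifier <- function(x, ...) {
  cat(sprintf("Bleeding-rank classifier (%s), trained on features in [%.4g, %.4g] x [%.4g, %.4g]\n",
              x$spec$kind, x$bounds[1, 1], x$bounds[2, 1], x$bounds[1, 2], x$bounds[2, 2]))
  invisible(x)
}

#' K-nearest-neighbour rank prediction
#'
#' Euclidean distance over the 2-d feature space; the predicted rank is the
#' majority label among the `k` nearest training points. Ties are broken by
#' the smaller mean distance among the tied labels, then by the lower score.
#'
#' @param train_features Numeric matrix of (normalized) training features.
#' @param train_labels Integer labels aligned with the rows.
#' @param query Numeric vector (one feature point).
#' @param k Neighbour count, at most the number of training points.
#' @return The predicted integer rank.
#' @export
knn_predict <- function(train_features, train_labels, query, k) {
  X <- as.matrix(train_features)
  if (nrow(X) == 0L) stop("empty training set")
  if (k > nrow(X)) stop("k exceeds the number of training points")
  d <- sqrt(colSums((t(X) - as.numeric(query))^2))
  ord <- order(d)                      # stable: ties keep input order
  nn <- ord[seq_len(k)]
  lab <- train_labels[nn]
  tab <- table(lab)
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1L) {
    meand <- vapply(best, function(l) mean(d[nn][lab == as.integer(l)]), 0)
    best <- best[meand == min(meand)]
    best <- min(as.integer(best))
  }
  as.integer(best[1])
}

#' Predict bleeding ranks for new videos
#'
#' @param object A fitted `"bleed_classifier"`.
#' @param newdata Matrix of raw (unnormalized) video features, or a list of
#'   [video_features()] results.
#' @param ... Unused.
#' @return Integer vector of predicted ranks in `{0, 1, 2, 3}`.
#' @export
predict.bleed_classifier <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  # normalize with the stored training bounds
  Xs <- X
  for (j in seq_len(ncol(X))) {
    rng <- object$bounds[2, j] - object$bounds[1, j]
    raw <- if (rng == 0) rep(0, nrow(X)) else (X[, j] - object$bounds[1, j]) / rng
    if (any(raw < -0.5 | raw > 1.5))
      warning("feature ", j, " far outside the training range; prediction may be unreliable")
    Xs[, j] <- pmin(pmax(raw, 0), 1)
  }
  spec <- object$spec
  out <- switch(spec$kind,
    knn = vapply(seq_len(nrow(Xs)), function(i)
      knn_predict(object$fit$X, object$fit$y, Xs[i, ], spec$knn_k), 0L),
    naive_bayes = as.integer(as.character(predict(object$fit, Xs))),
    random_forest = as.integer(as.character(predict(object$fit, Xs))),
    svm = as.integer(as.character(predict(object$fit, Xs)))
  )
  out
}

#' Naive Bayes class posteriors for a feature point
#'
#' Exposed mainly for diagnostics: the four posteriors sum to one.
#'
#' @param object A fitted `"bleed_classifier"` of kind `"naive_bayes"`.
#' @param newdata Raw feature matrix.
#' @return Matrix of class posteriors (rows = inputs, columns = ranks 0-3).
#' @export
nb_posterior <- function(object, newdata) {
  stopifnot(inherits(object, "bleed_classifier"), object$spec$kind == "naive_bayes")
  X <- as_feature_matrix(newdata)
  Xs <- X
  for (j in seq_len(ncol(X))) {
    rng <- object$bounds[2, j] - object$bounds[1, j]
    Xs[, j] <- if (rng == 0) 0 else pmin(pmax((X[, j] - object$bounds[1, j]) / rng, 0), 1)
  }
  predict(object$fit, Xs, type = "raw")
}

#' Save / load a fitted rank classifier
#'
#' @param object A `"bleed_classifier"`.
#' @param path File path.
#' @return `load_classifier()` returns the classifier; `save_classifier()`
#'   returns `path` invisibly.
#' @export
save_classifier <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "bleed_classifier")) stop("not a classifier file: ", path)
  obj
}
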