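# Helper: four tight, well-separated clusters, one per rank, in the raw
# feature space (ratio in [0,1], counts on a larger scale, as the pipeline
# produces them).
separable_clusters <- function(n_per_class = 10, sd = 0.004, seed = 1) {
  centers_ratio <- c(0.05, 0.3, 0.6, 0.9)
  centers_count <- c(2, 6, 11, 16)
  set.seed(seed)
  X <- do.call(rbind, lapply(0:3, function(lv)
    cbind(rnorm(n_per_class, centers_ratio[lv + 1], sd),
          rnorm(n_per_class, centers_count[lv + 1], sd * 40))))
  list(X = X, y = rep(0:3, each = n_per_class),
       centers = cbind(centers_ratio, centers_count))
}

test_that("consensus labeling follows the three-evaluator majority rule", {
  expect_equal(consensus_label(c(2, 2, 2)), 2L)
  expect_equal(consensus_label(c(1, 1, 3)), 1L)
  expect_equal(consensus_label(c(3, 1, 1)), 1L)
  expect_true(is.na(consensus_label(c(0, 1, 2))))
  expect_error(consensus_label(c(0, 1, 4)), "\\[0, 3\\]")
  expect_error(consensus_label(c(1, 2)), "three")
})

test_that("train/val split is stratified, deterministic and a partition", {
  ids <- sprintf("v%02d", 1:40)
  labels <- rep(0:3, each = 10)
  sp <- split_train_val(ids, labels, 0.10, seed = 4)
  expect_length(sp$val, 4)
  per_class <- table(labels[match(sp$val, ids)])
  expect_true(max(per_class) - min(per_class) <= 1)
  expect_setequal(c(sp$train, sp$val), ids)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_identical(sp, split_train_val(ids, labels, 0.10, seed = 4))
  expect_error(split_train_val(ids, labels, 0, seed = 1), "val_fraction")
  expect_error(split_train_val(ids, labels, 1, seed = 1), "val_fraction")
})

test_that("knn prediction equals the exhaustive-scan oracle", {
  set.seed(7)
  X <- matrix(runif(100), 50, 2)
  y <- sample(0:3, 50, replace = TRUE)
  for (k in c(1, 3, 5)) {
    for (i in 1:100) {
      q <- runif(2)
      expect_identical(knn_predict(X, y, q, k), oracle_knn(X, y, q, k))
    }
  }
  # zero distance with k=1 returns that training label
  expect_equal(knn_predict(X, y, X[17, ], 1), y[17])
  # documented majority example: neighbours labelled (2,2,3) -> 2
  X3 <- rbind(c(0, 0), c(0.01, 0), c(0.1, 0))
  expect_equal(knn_predict(X3, c(2L, 2L, 3L), c(0, 0), 3), 2L)
  expect_error(knn_predict(X[0, , drop = FALSE], integer(0), c(0, 0), 1), "empty")
  expect_error(knn_predict(X, y, c(0, 0), 51), "exceeds")
})

test_that("all four classifiers separate well-separated clusters", {
  tr <- separable_clusters(10, sd = 0.002, seed = 11)
  te <- separable_clusters(10, sd = 0.002, seed = 12)
  for (kind in c("knn", "naive_bayes", "random_forest", "svm")) {
    model <- train_classifier(classifier_spec(kind, seed = 1), tr$X, tr$y)
    expect_equal(predict(model, tr$X), tr$y, info = kind)       # train acc 1
    acc <- mean(predict(model, te$X) == te$y)
    expect_gte(acc, 0.95)
    # cluster centers go to their own class
    expect_equal(predict(model, tr$centers), 0:3, info = kind)
  }
})

test_that("classifier training contracts: errors and determinism", {
  tr <- separable_clusters(6, seed = 2)
  expect_error(train_classifier(classifier_spec("svm"), tr$X[1:6, ], rep(0L, 6)),
               "single class")
  expect_error(train_classifier(classifier_spec("svm"), tr$X, tr$y[-1]),
               "length")
  expect_error(train_classifier(classifier_spec("knn", knn_k = 25), tr$X[1:8, ],
                                tr$y[1:8]),
               "exceeds")
  # refits with the same seed predict identically (stochastic learners)
  for (kind in c("random_forest", "svm")) {
    m1 <- train_classifier(classifier_spec(kind, seed = 5), tr$X, tr$y)
    m2 <- train_classifier(classifier_spec(kind, seed = 5), tr$X, tr$y)
    q <- separable_clusters(3, seed = 30)$X
    expect_identical(predict(m1, q), predict(m2, q))
  }
})

test_that("knn and naive Bayes are invariant to training-order permutation", {
  tr <- separable_clusters(8, sd = 0.01, seed = 21)
  set.seed(99)
  perm <- sample(nrow(tr$X))
  q <- separable_clusters(5, sd = 0.05, seed = 22)$X
  for (kind in c("knn", "naive_bayes")) {
    m1 <- train_classifier(classifier_spec(kind), tr$X, tr$y)
    m2 <- train_classifier(classifier_spec(kind), tr$X[perm, ], tr$y[perm])
    expect_identical(predict(m1, q), predict(m2, q))
  }
})

test_that("naive Bayes posteriors are a probability distribution", {
  tr <- separable_clusters(8, seed = 31)
  m <- train_classifier(classifier_spec("naive_bayes"), tr$X, tr$y)
  post <- nb_posterior(m, separable_clusters(5, seed = 32)$X)
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9)
})

test_that("predictions are always in 0..3 and warn on far out-of-range input", {
  tr <- separable_clusters(6, seed = 41)
  m <- train_classifier(classifier_spec("knn"), tr$X, tr$y)
  set.seed(5)
  q <- cbind(runif(50, 0.05, 0.9), runif(50, 2, 16))
  p <- predict(m, q)
  expect_true(all(p %in% 0:3))
  expect_warning(predict(m, cbind(0.5, 100)), "outside the training range")
  expect_identical(predict(m, q), predict(m, q))
})

test_that("classifier serialization round-trips", {
  tr <- separable_clusters(6, seed = 51)
  m <- train_classifier(classifier_spec("svm"), tr$X, tr$y)
  p <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, p)
  m2 <- load_classifier(p)
  q <- separable_clusters(4, seed = 52)$X
  expect_identical(predict(m, q), predict(m2, q))
})
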