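# The segmentation network and its metrics. Small configurations keep these
# fast; the full train-and-generalise check lives in the acceptance suite.

test_that("network output matches the input resolution with sigmoid range", {
  m <- build_resunet(resunet_config(c(64, 64), base_filters = 4, depth = 3), seed = 1)
  X <- array(runif(64 * 64 * 3), c(1, 64, 64, 3))
  z <- bleedrank:::resunet_forward(m, X)
  expect_equal(dim(z), c(1L, 64L, 64L, 1L))
  p <- 1 / (1 + exp(-z))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("input sizes not divisible by 2^depth are a configuration error", {
  expect_error(resunet_config(c(60, 60), 8, 3), "divisible")
  expect_error(resunet_config(c(64, 60), 8, 3), "divisible")
  expect_silent(resunet_config(c(48, 64), 8, 2))
  expect_error(resunet_config(c(64, 64), 2, 3), "base_filters")
})

test_that("zero final-layer weights give probability one half everywhere", {
  m <- build_resunet(resunet_config(c(32, 32), 4, 2), seed = 2)
  m$params$final.W[] <- 0
  m$params$final.b[] <- 0
  X <- array(runif(32 * 32 * 3), c(1, 32, 32, 3))
  z <- bleedrank:::resunet_forward(m, X)
  expect_true(all(z == 0))
  # strict > at threshold 0.5 -> empty mask; threshold 0 -> full mask
  fr <- array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
  expect_equal(sum(predict_loop_mask(m, fr, 0.5)), 0)
  expect_equal(sum(predict_loop_mask(m, fr, 0)), 32 * 32)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  m <- build_resunet(resunet_config(c(8, 8), 4, 1), seed = 3)
  X <- array(runif(2 * 8 * 8 * 3), c(2, 8, 8, 3))
  G <- array(rbinom(2 * 64, 1, 0.3), c(2, 8, 8, 1))
  lossfn <- function(model) {
    z <- bleedrank:::resunet_forward(model, X)
    bleedrank:::seg_loss_grad(z, G, "bce+dice")$loss
  }
  fw <- bleedrank:::resunet_forward(m, X, want_cache = TRUE)
  lg <- bleedrank:::seg_loss_grad(fw$logits, G, "bce+dice")
  gr <- bleedrank:::resunet_backward(m, fw$cache, array(lg$dz, dim(fw$logits)))
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      mp <- m; mp$params[[nm]][i] <- p[i] + 1e-6
      mm <- m; mm$params[[nm]][i] <- p[i] - 1e-6
      num <- (lossfn(mp) - lossfn(mm)) / 2e-6
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training descends and epochs=0 returns the model untrained", {
  sf <- generate_frame(1, TRUE, c(32, 32), seed = 4)
  m0 <- build_resunet(resunet_config(c(32, 32), 4, 2), seed = 1)
  m_none <- train_segmenter(list(sf$frame), list(sf$loop_mask),
                            seg_train_config(epochs = 0, seed = 1), m0)
  expect_length(m_none$history, 0)
  expect_identical(m_none$params, m0$params)
  m_tr <- train_segmenter(list(sf$frame), list(sf$loop_mask),
                          seg_train_config(epochs = 30, batch_size = 1,
                                           learning_rate = 3e-3, seed = 1), m0)
  expect_length(m_tr$history, 30)
  expect_lt(m_tr$history[30], m_tr$history[1])
  # shape-mismatched pairs are rejected
  expect_error(train_segmenter(list(sf$frame), list(matrix(FALSE, 16, 16)),
                               seg_train_config(epochs = 1), m0),
               "mismatch")
})

test_that("checkpoint round-trip reproduces predictions bit-identically", {
  m <- build_resunet(resunet_config(c(32, 32), 4, 2), seed = 7)
  p <- withr::local_tempfile(fileext = ".rds")
  save_resunet(m, p)
  m2 <- load_resunet(p)
  fr <- array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
  expect_identical(predict_loop_mask(m, fr), predict_loop_mask(m2, fr))
  expect_identical(bleedrank:::resunet_forward(m, array(fr / 255, c(1, 32, 32, 3))),
                   bleedrank:::resunet_forward(m2, array(fr / 255, c(1, 32, 32, 3))))
})

test_that("iou and dice match brute-force counting and their identity", {
  a <- matrix(FALSE, 8, 8); a[3:4, 3:4] <- TRUE        # 2x2 block
  b <- matrix(FALSE, 8, 8); b[3:4, 3:6] <- TRUE        # 2x4 block
  expect_equal(iou(a, b), 0.5)
  expect_equal(dice(a, b), 2 / 3)
  expect_equal(iou(a, a), 1.0)
  disj <- matrix(FALSE, 8, 8); disj[7:8, 7:8] <- TRUE
  expect_equal(iou(a, disj), 0.0)
  expect_equal(dice(a, disj), 0.0)
  empty <- matrix(FALSE, 8, 8)
  expect_equal(iou(empty, empty), 1.0)
  expect_equal(dice(empty, empty), 1.0)
  expect_error(iou(a, matrix(FALSE, 4, 4)), "shape")
  set.seed(9)
  for (i in 1:100) {
    x <- random_mask(16, 16); y <- random_mask(16, 16)
    expect_identical(iou(x, y), oracle_iou(x, y))
    expect_identical(dice(x, y), oracle_dice(x, y))
    expect_equal(dice(x, y), 2 * iou(x, y) / (1 + iou(x, y)), tolerance = 1e-12)
    # symmetry and transposition invariance
    expect_identical(iou(x, y), iou(y, x))
    expect_identical(iou(t(x), t(y)), iou(x, y))
  }
})
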