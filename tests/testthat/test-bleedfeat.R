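test_that("YCbCr conversion matches the BT.601 full-range coefficients", {
  px <- function(r, g, b) array(rep(c(r, g, b), each = 4), c(2, 2, 3))
  gray <- rgb_to_ycbcr(px(128, 128, 128))
  expect_equal(c(gray$Y, gray$Cb, gray$Cr), rep(128, 12))
  black <- rgb_to_ycbcr(px(0, 0, 0))
  expect_equal(c(black$Y[1, 1], black$Cb[1, 1], black$Cr[1, 1]), c(0, 128, 128))
  red <- rgb_to_ycbcr(px(255, 0, 0))
  expect_equal(red$Y[1, 1], 76.245, tolerance = 1e-3)
  expect_equal(red$Cb[1, 1], 84.972, tolerance = 1e-2)
  expect_equal(red$Cr[1, 1], 255)  # 255.5 clipped
})

test_that("red mask thresholds behave as documented", {
  pure_red <- array(0, c(4, 4, 3)); pure_red[, , 1] <- 255
  expect_true(all(extract_red_mask(rgb_to_ycbcr(pure_red))))
  gray <- array(128, c(4, 4, 3))
  expect_false(any(extract_red_mask(rgb_to_ycbcr(gray))))
  # custom thresholds are honoured: raising cr_min excludes darker reds
  blood <- array(rep(c(150, 30, 40), each = 4), c(2, 2, 3))  # Cr ~ 187
  expect_true(all(extract_red_mask(rgb_to_ycbcr(blood))))
  expect_false(any(extract_red_mask(rgb_to_ycbcr(blood), red_thresholds(cr_min = 200))))
  expect_error(red_thresholds(cr_min = 300), "255")
})

test_that("loop elimination is red AND NOT loop, with identity/annihilator laws", {
  set.seed(3)
  red <- random_mask(10, 10, 0.5)
  empty <- matrix(FALSE, 10, 10)
  full <- matrix(TRUE, 10, 10)
  expect_identical(eliminate_loop(red, empty), red)
  expect_identical(eliminate_loop(red, full), empty)
  # overlap accounting: block red mask loses exactly the overlap pixels
  red2 <- matrix(FALSE, 10, 10); red2[1:5, 1:5] <- TRUE   # 25 px
  loop <- matrix(FALSE, 10, 10); loop[4:5, 4:5] <- TRUE   # overlap 4 px
  expect_equal(sum(eliminate_loop(red2, loop)), 25 - 4)
  expect_error(eliminate_loop(red, matrix(FALSE, 4, 4)), "shape")
})

test_that("region counting agrees with a flood-fill oracle for both connectivities", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE; m[7:9, 7:9] <- TRUE
  expect_equal(count_bleeding_regions(m, 8), 2L)
  expect_equal(count_bleeding_regions(matrix(FALSE, 5, 5), 8), 0L)
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_equal(count_bleeding_regions(single, 8, min_area = 20), 0L)
  # diagonal touch: one region under 8-connectivity, two under 4
  diagm <- matrix(FALSE, 4, 4); diagm[1, 1] <- TRUE; diagm[2, 2] <- TRUE
  expect_equal(count_bleeding_regions(diagm, 8), 1L)
  expect_equal(count_bleeding_regions(diagm, 4), 2L)
  set.seed(17)
  for (i in 1:200) {
    mk <- random_mask(16, 16, runif(1, 0.2, 0.6))
    conn <- if (i %% 2) 4L else 8L
    expect_identical(count_bleeding_regions(mk, conn),
                     oracle_count_regions(mk, conn))
  }
  # min_area filtering agrees with the oracle too
  set.seed(18)
  for (i in 1:20) {
    mk <- random_mask(16, 16, 0.4)
    expect_identical(count_bleeding_regions(mk, 8, min_area = 3),
                     oracle_count_regions(mk, 8, min_area = 3))
  }
})

test_that("bleeding ratio counts blood over valid pixels only", {
  blood <- matrix(FALSE, 10, 10); blood[1:5, 1:5] <- TRUE   # 25 px
  valid <- matrix(TRUE, 10, 10)
  expect_equal(bleeding_ratio(blood, valid), 0.25)
  expect_equal(bleeding_ratio(valid, valid), 1.0)
  expect_equal(bleeding_ratio(matrix(FALSE, 10, 10), valid), 0.0)
  expect_error(bleeding_ratio(blood, matrix(FALSE, 10, 10)), "fully occluded")
})

test_that("loop elimination never raises the bleeding ratio and is strict with glow", {
  for (s in 1:10) {
    sf <- generate_frame(2, loop_present = TRUE, c(64, 64), seed = 300 + s)
    red <- extract_red_mask(rgb_to_ycbcr(sf$frame))
    before <- bleeding_ratio(red, matrix(TRUE, 64, 64))
    after <- bleeding_ratio(eliminate_loop(red, sf$loop_mask), !sf$loop_mask)
    expect_lte(after, before)
  }
  # the red glow makes the inequality strict
  sf <- generate_frame(0, loop_present = TRUE, c(64, 64), seed = 41)
  red <- extract_red_mask(rgb_to_ycbcr(sf$frame))
  expect_lt(bleeding_ratio(eliminate_loop(red, sf$loop_mask), !sf$loop_mask),
            bleeding_ratio(red, matrix(TRUE, 64, 64)))
})

test_that("video features average per-frame features arithmetically", {
  f1 <- generate_frame(3, FALSE, c(64, 64), seed = 1)
  f2 <- generate_frame(0, FALSE, c(64, 64), seed = 2)
  single <- video_features(list(f1$frame))
  ff <- frame_features(f1$frame)
  expect_equal(single$mean_bleeding_ratio, ff$bleeding_ratio)
  expect_equal(single$mean_region_count, ff$region_count)
  both <- video_features(list(f1$frame, f2$frame))
  ff2 <- frame_features(f2$frame)
  expect_equal(both$mean_bleeding_ratio, (ff$bleeding_ratio + ff2$bleeding_ratio) / 2)
  # blood-free frames give (0, 0)
  blank <- array(128, c(64, 64, 3))
  expect_equal(video_features(list(blank, blank)),
               list(mean_bleeding_ratio = 0, mean_region_count = 0))
  expect_error(video_features(list()), "empty")
})

test_that("mean bleeding ratio strictly increases across levels", {
  per_level <- vapply(0:3, function(lv) {
    mean(vapply(1:10, function(v) {
      vid <- generate_video(lv, n_frames = 5, loop_present = FALSE,
                            seed = 500 + v, size = c(64, 64))
      video_features(lapply(vid$frames, `[[`, "frame"))$mean_bleeding_ratio
    }, 0))
  }, 0)
  expect_true(all(diff(per_level) > 0))
})

test_that("debug panels reconstruct the frame chain on disk", {
  dir <- withr::local_tempdir()
  sf <- generate_frame(2, loop_present = TRUE, c(48, 48), seed = 77)
  paths <- write_debug_panels(sf$frame, sf$loop_mask, file.path(dir, "f1"))
  expect_true(all(file.exists(paths)))
  red <- load_mask(paths[2])
  bleeding <- load_mask(paths[4])
  expect_identical(bleeding, eliminate_loop(red, sf$loop_mask))
  # loop pixels are blacked out in the eliminated view
  noloop <- load_frame(paths[3])
  expect_true(all(noloop[, , 1][sf$loop_mask] == 0))
})

test_that("min-max normalization is fitted on train and clips applied values", {
  train <- cbind(c(0.1, 0.2, 0.3), c(5, 10, 15))
  nrm <- normalize_features(train, apply_to = cbind(c(0.05, 0.2, 0.4), c(10, 10, 10)))
  expect_equal(nrm$train[, 1], c(0, 0.5, 1))
  expect_equal(nrm$train[, 2], c(0, 0.5, 1))
  expect_equal(nrm$applied[, 1], c(0, 0.5, 1))  # clipped at both ends
  expect_equal(nrm$applied[, 2], c(0.5, 0.5, 0.5))
  # constant training column maps to zero
  const <- normalize_features(cbind(c(1, 1, 1), c(0, 1, 2)))
  expect_equal(const$train[, 1], c(0, 0, 0))
  expect_error(normalize_features(matrix(nrow = 0, ncol = 2)), "non-empty")
})
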