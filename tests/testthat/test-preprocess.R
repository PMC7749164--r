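test_that("grayscale conversion applies BT.601 weights and handles edge cases", {
  red <- array(c(255, 0, 0), dim = c(1, 1, 3))
  expect_equal(as.numeric(to_grayscale(red)), 76)  # round(0.299 * 255)
  white <- array(255, dim = c(1, 1, 3))
  expect_equal(as.numeric(to_grayscale(white)), 255)
  g <- matrix(c(10, 20, 30, 40), 2, 2)
  expect_equal(unclass(to_grayscale(g)), g, ignore_attr = TRUE)
  expect_error(to_grayscale(matrix(numeric(0), 0, 0)), "no pixels")
})

test_that("trim returns the exact top-left window and validates size", {
  img <- as_gray_image(matrix(seq_len(1600 * 1250) %% 256, 1250, 1600))
  out <- trim_image(img)
  expect_equal(dim(out), c(1200, 1400))
  expect_equal(unclass(out), unclass(img)[1:1200, 1:1400], ignore_attr = TRUE)
  same <- as_gray_image(matrix(0, 40, 50))
  expect_equal(dim(trim_image(same, 50, 40)), c(40, 50))
  expect_error(trim_image(as_gray_image(matrix(0, 100, 100))), "smaller")
})

test_that("wavelet reconstruction is an identity with all levels and zero with none", {
  set.seed(11)
  img <- as_gray_image(matrix(sample(0:255, 96 * 80, replace = TRUE), 80, 96))
  full <- wavelet_reconstruct(img, 0:10)
  expect_lt(max(abs(unclass(full) - unclass(img))), 1)
  none <- wavelet_reconstruct(img, integer(0))
  expect_true(all(unclass(none) == 0))
  expect_error(wavelet_reconstruct(img, c(3, 11)), "0..10")
})

test_that("dropping coarse wavelet levels flattens a brightness gradient", {
  # 256 columns so the coarse levels carry the ramp; keeping levels 4-10
  # removes the approximation and the broad-scale components
  img <- as_gray_image(round(matrix(rep(seq(78, 178, length.out = 256),
                                        each = 32), 32, 256)))
  rec <- wavelet_reconstruct(img, 4:10)
  span <- function(m) { cm <- colMeans(unclass(m)); max(cm) - min(cm) }
  expect_lt(span(rec), span(img) / 2)
})

test_that("Otsu matches the exhaustive 256-threshold search", {
  # two-mode example: 40 pixels at 50, 60 at 200
  v <- as_gray_image(matrix(c(rep(50, 40), rep(200, 60)), 10, 10))
  res <- binarize_otsu(v)
  expect_equal(res$threshold, otsu_oracle(unclass(v)))
  expect_equal(sum(res$binary == 1), 60)
  # checkerboard of 0 and 255
  cb <- as_gray_image(outer(1:8, 1:8, function(i, j) ((i + j) %% 2) * 255))
  res_cb <- binarize_otsu(cb)
  expect_equal(unclass(res_cb$binary), (unclass(cb) == 255) + 0,
               ignore_attr = TRUE)
  # constant image: degenerate, threshold at the constant, all one label
  res_const <- binarize_otsu(as_gray_image(matrix(100, 5, 5)))
  expect_equal(res_const$threshold, 100)
  expect_true(all(res_const$binary == 0))
  # property: exact agreement with brute force on random images
  set.seed(21)
  for (i in 1:100) {
    m <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    expect_equal(binarize_otsu(as_gray_image(m))$threshold, otsu_oracle(m))
  }
})

test_that("erosion matches hand application of the cross element", {
  all_white <- as_binary_image(matrix(1, 5, 5))
  once <- erode_binary(all_white, 1)
  expected <- matrix(0, 5, 5); expected[2:4, 2:4] <- 1
  expect_equal(unclass(once), expected, ignore_attr = TRUE)
  expect_equal(unclass(erode_binary(all_white, 0)), unclass(all_white),
               ignore_attr = TRUE)
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_true(all(erode_binary(as_binary_image(single), 1) == 0))
  expect_error(erode_binary(all_white, -1), "non-negative")
})

test_that("erosion is anti-extensive and monotone in iterations", {
  set.seed(31)
  for (i in 1:20) {
    img <- as_binary_image(random_mask(12, 15, 0.7))
    e1 <- erode_binary(img, 1)
    e2 <- erode_binary(img, 2)
    expect_true(all(e1 <= unclass(img)))
    expect_true(all(e2 <= unclass(e1)))
    expect_equal(dim(e1), dim(img))
  }
})
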