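test_that("kNN density matches the exhaustive-sort oracle on known geometry", {
  # two white pixels at opposite corners of a 20x20 image, k = 1
  m <- matrix(0, 20, 20); m[1, 1] <- 1; m[20, 20] <- 1
  fld <- knn_density(as_binary_image(m), k = 1, spacing = 1)
  # the centre node's nearest white pixel is the (20, 20) corner at sqrt(162)
  expect_equal(fld$values[11, 11], 1 / (2 * pi * sum((c(20, 20) - c(11, 11))^2)))
  expect_equal(fld$values, knn_field_oracle(m, 1, 1))
  # node coinciding with a white pixel: capped to the max finite density
  expect_equal(fld$values[1, 1], max(fld$values))
})

test_that("kNN density grid covers the frame at the requested spacing", {
  m <- random_mask(120, 140, 0.5)
  fld <- knn_density(as_binary_image(m), k = 10, spacing = 10)
  expect_equal(dim(fld$values), c(12, 14))
  expect_equal(fld$spacing, 10)
  expect_error(knn_density(as_binary_image(matrix(c(1, rep(0, 24)), 5, 5)),
                           k = 100),
               "k = 100")
})

test_that("kNN density equals the exhaustive oracle on random images", {
  set.seed(41)
  for (i in 1:50) {
    k <- sample(c(1, 3, 10), 1)
    m <- random_mask(20, 20, 0.4)
    while (sum(m) < k) m <- random_mask(20, 20, 0.4)
    fld <- knn_density(as_binary_image(m), k = k, spacing = 3)
    expect_equal(fld$values, knn_field_oracle(m, k, 3), tolerance = 1e-12)
  }
})

test_that("kNN density is invariant to translating white set and grid together", {
  set.seed(42)
  m <- random_mask(18, 18, 0.4)
  big <- matrix(0, 24, 24)
  big[4 + seq_len(18), 4 + seq_len(18)] <- m
  f1 <- knn_density(as_binary_image(m), k = 3, spacing = 1)
  f2 <- knn_density(as_binary_image(big), k = 3, spacing = 1)
  expect_equal(f2$values[4 + seq_len(18), 4 + seq_len(18)], f1$values,
               tolerance = 1e-12)
})

test_that("signed distance matches the exhaustive Manhattan oracle", {
  m13 <- matrix(c(1, 0, 1), 1, 3)
  expect_equal(signed_distance(as_binary_image(m13))$values,
               matrix(c(1, -1, 1), 1, 3))
  ring <- matrix(1, 5, 5); ring[3, 3] <- 0
  v <- signed_distance(as_binary_image(ring))$values
  expect_equal(v[3, 3], -1)
  expect_equal(v[2, 3], 1)
  expect_equal(v[1, 1], 4)  # Manhattan distance from corner to the centre
  set.seed(51)
  for (i in 1:50) {
    m <- random_mask(12, 14, runif(1, 0.2, 0.8))
    expect_equal(signed_distance(as_binary_image(m))$values,
                 signed_distance_oracle(m))
  }
})

test_that("signed distance handles one-colour images with the size sentinel", {
  expect_true(all(signed_distance(as_binary_image(matrix(1, 5, 5)))$values == 10))
  expect_true(all(signed_distance(as_binary_image(matrix(0, 5, 5)))$values == -10))
})

test_that("signed distance is Lipschitz within each colour and sign-consistent", {
  # Within one colour the map is 1-Lipschitz; across the border the +1/-1
  # convention makes adjacent values differ by exactly 2, never more.
  set.seed(61)
  for (i in 1:20) {
    m <- random_mask(10, 12, 0.5)
    v <- signed_distance(as_binary_image(m))$values
    expect_true(all(sign(v) == ifelse(m == 1, 1, -1)))
    same_col_r <- m[-nrow(m), ] == m[-1, ]
    expect_true(all(abs(diff(v))[same_col_r] <= 1))
    expect_true(all(abs(diff(v))[!same_col_r] == 2))
    same_col_c <- m[, -ncol(m)] == m[, -1]
    dc <- t(diff(t(v)))
    expect_true(all(abs(dc)[same_col_c] <= 1))
    expect_true(all(abs(dc)[!same_col_c] == 2))
  }
})

test_that("grayscale filtration is the identity at spacing 1", {
  g <- as_gray_image(matrix(c(0, 255, 255, 0), 2, 2))
  fld <- grayscale_filtration(g)
  expect_equal(fld$values, unclass(g), ignore_attr = TRUE)
  expect_equal(fld$spacing, 1)
  cst <- grayscale_filtration(as_gray_image(matrix(128, 3, 3)))
  expect_true(all(cst$values == 128))
})
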