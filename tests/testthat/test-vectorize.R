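# build a diagram object directly from a points table (test convenience)
fake_diagram <- function(dim, birth, death) {
  skintda:::new_persistence_diagram(
    tibble::tibble(dim = as.integer(dim), birth = birth, death = death,
                   birth_row = 1L, birth_col = 1L, death_row = 1L,
                   death_col = 1L, essential = FALSE),
    source = "test")
}

test_that("fitting the vectorizer fixes ranges and weight from training only", {
  d1 <- fake_diagram(c(0, 1), c(4, 3), c(0, 1))   # mids 2, 2; lives 4, 2
  d2 <- fake_diagram(c(0, 1), c(2, 5), c(-2, 1))  # mids 0, 3; lives 4, 4
  cfg <- fit_vectorizer(list(d1, d2), method = "counts")
  expect_equal(cfg$ranges$dim0$mid, c(0, 2))
  expect_equal(cfg$ranges$dim1$mid, c(2, 3))
  expect_equal(cfg$weight_max, 4)  # the largest life-time seen anywhere
  # degenerate single-point range gets a fixed 5% margin
  cfg1 <- fit_vectorizer(list(fake_diagram(0, 4, 0)))
  expect_gt(diff(cfg1$ranges$dim0$mid), 0)
  expect_error(fit_vectorizer(list()), "empty")
})

test_that("count vectors conserve points, clip outside, and use half-open bins", {
  train <- fake_diagram(c(0, 0), c(10, 0), c(0, -10))  # dim0 mids -5..5
  cfg <- fit_vectorizer(list(train), method = "counts")
  expect_length(vectorize_diagram(train, cfg), 800)
  # empty diagram -> zero vector
  empty <- fake_diagram(integer(0), numeric(0), numeric(0))
  expect_true(all(vectorize_diagram(empty, cfg) == 0))
  # three identical points land in one region, total conserved
  d3 <- fake_diagram(c(0, 0, 0), c(2, 2, 2), c(0, 0, 0))
  v3 <- vectorize_diagram(d3, cfg)
  expect_equal(sum(v3), 3)
  expect_equal(max(v3), 3)
  # far outside the fitted range: clipped into a boundary region, not lost
  d_out <- fake_diagram(0, 1e3, 990)
  expect_equal(sum(vectorize_diagram(d_out, cfg)), 1)
  # a point exactly on an interior boundary joins the upper region
  edges <- seq(cfg$ranges$dim0$mid[1], cfg$ranges$dim0$mid[2],
               length.out = 21)
  mid_on_edge <- edges[3]
  d_edge <- fake_diagram(0, mid_on_edge + 0.5, mid_on_edge - 0.5)  # life 1
  v <- matrix(vectorize_diagram(d_edge, cfg)[1:400], 20, 20)
  expect_equal(unname(which(rowSums(v) > 0)), 3)
})

test_that("persistence image mass matches numeric integration for a max-weight point", {
  # a config whose range comfortably contains a unit-weight point
  # (life = weight_max) so the full Gaussian mass falls inside
  cfg <- structure(
    list(method = "persistence_image", grid = c(20L, 20L), sigma = 0.5,
         dims = c(0, 1),
         ranges = list(dim0 = list(mid = c(-10, 10), life = c(0, 20)),
                       dim1 = list(mid = c(0, 1), life = c(0, 1))),
         weight_max = 10),
    class = "pd_vectorizer")
  pt <- fake_diagram(0, 5, -5)  # mid 0, life 10 = weight_max
  v <- vectorize_diagram(pt, cfg)
  expect_length(v, 800)
  expect_true(all(v >= 0))
  num <- pi_mass_numeric(0, 10, cfg$ranges$dim0, 0.5, cfg$weight_max)
  expect_lt(abs(sum(v[1:400]) - num), 1e-3)
  expect_lt(abs(sum(v[1:400]) - 1), 1e-3)  # tails are negligible here
})

test_that("persistence image is linear in the diagram and weight-monotone", {
  train <- fake_diagram(c(0, 0), c(12, -2), c(2, -12))
  cfg <- fit_vectorizer(list(train), sigma = 1)
  a <- fake_diagram(0, 8, 2)
  b <- fake_diagram(0, 2, -6)
  ab <- fake_diagram(c(0, 0), c(8, 2), c(2, -6))
  expect_equal(vectorize_diagram(ab, cfg),
               vectorize_diagram(a, cfg) + vectorize_diagram(b, cfg))
  # increasing a point's life-time never decreases total mass
  low <- sum(vectorize_diagram(fake_diagram(0, 3, 1), cfg))
  high <- sum(vectorize_diagram(fake_diagram(0, 4, 0), cfg))
  expect_gte(high, low)
})

test_that("persistence image is continuous under small point moves", {
  train <- fake_diagram(c(0, 0), c(12, -2), c(2, -12))
  cfg <- fit_vectorizer(list(train), sigma = 1)
  delta <- 0.01
  v1 <- vectorize_diagram(fake_diagram(0, 6, 2), cfg)
  v2 <- vectorize_diagram(fake_diagram(0, 6 + delta, 2 + delta), cfg)
  expect_lt(sum(abs(v1 - v2)), 10 * delta / cfg$sigma)
})

test_that("near-zero-variance filter applies the documented frequency rule", {
  set.seed(81)
  d <- tibble::tibble(
    all_zero = rep(0, 100),
    rare = c(rep(0, 98), 1, 1),             # ratio 49 > 19, 2% unique -> drop
    distinct = seq_len(100),                # all distinct -> keep
    frequent = rep(c(0, 1), 50)             # ratio 1 -> keep
  )
  res <- drop_near_zero_variance(d)
  expect_setequal(res$kept, c("distinct", "frequent"))
  expect_equal(names(res$data), c("distinct", "frequent"))
  expect_error(drop_near_zero_variance(d[1, ]), "2 rows")
})
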