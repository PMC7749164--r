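test_that("hand-checked fields give the expected pairs and positions", {
  # constant field: one essential component, no holes
  d <- compute_persistence(matrix(7, 4, 4))
  expect_equal(nrow(d), 1)
  expect_true(d$essential[1])
  expect_equal(c(d$birth, d$death), c(7, 7))

  # bright ring around a dark pit: one essential component and one hole
  # born with the ring, filled at the centre
  f <- matrix(200, 3, 3); f[2, 2] <- 0
  d <- compute_persistence(f)
  expect_equal(sort(d$dim), c(0, 1))
  ess <- d[d$essential, ]
  expect_equal(c(ess$birth, ess$death), c(200, 0))
  hole <- d[d$dim == 1, ]
  expect_equal(c(hole$birth, hole$death), c(200, 0))
  expect_equal(c(hole$death_row, hole$death_col), c(2, 2))

  # two peaks joined by a saddle ridge: younger peak dies at the saddle
  g <- matrix(1, 3, 3)
  g[2, 1] <- 10; g[2, 2] <- 4; g[2, 3] <- 8
  d <- compute_persistence(g)
  d0 <- d[d$dim == 0 & !d$essential, ]
  expect_equal(nrow(d0), 1)
  expect_equal(c(d0$birth, d0$death), c(8, 4))
  expect_equal(c(d0$death_row, d0$death_col), c(2, 2))
  expect_equal(d[d$essential, ]$birth, 10)
  expect_equal(d[d$essential, ]$death, 1)
})

test_that("diagrams reproduce the Betti numbers of every superlevel set", {
  set.seed(71)
  for (i in 1:200) {
    f <- random_field(8, 8)
    d <- compute_persistence(f)
    sweep <- betti_sweep_oracle(f)
    for (r in seq_len(nrow(sweep))) {
      b <- betti_from_diagram(d, sweep$t[r])
      expect_equal(unname(b["b0"]), sweep$b0[r])
      expect_equal(unname(b["b1"]), sweep$b1[r])
    }
  }
})

test_that("alive pair counts satisfy the Euler relation at every threshold", {
  set.seed(72)
  for (i in 1:50) {
    f <- random_field(8, 8)
    d <- compute_persistence(f)
    for (t in sort(unique(as.vector(f)))) {
      b <- betti_from_diagram(d, t)
      expect_equal(unname(b["b0"] - b["b1"]), euler_oracle(f >= t))
    }
  }
})

test_that("sup-norm perturbations move diagrams by at most epsilon (stability)", {
  set.seed(73)
  for (i in 1:20) {
    f <- random_field(6, 6, n_levels = 8)
    eps <- runif(1, 0.05, 0.45)
    g <- f + matrix(runif(length(f), -eps, eps), nrow(f))
    d_f <- compute_persistence(f)
    d_g <- compute_persistence(g)
    for (dm in 0:1) {
      p1 <- as.matrix(d_f[d_f$dim == dm, c("birth", "death")])
      p2 <- as.matrix(d_g[d_g$dim == dm, c("birth", "death")])
      expect_true(bottleneck_leq(p1, p2, eps))
    }
  }
})

test_that("adding a constant shifts births and deaths, preserving pair count", {
  set.seed(74)
  f <- random_field(7, 7)
  d1 <- compute_persistence(f)
  d2 <- compute_persistence(f + 13.5)
  expect_equal(nrow(d1), nrow(d2))
  o1 <- order(d1$dim, d1$birth, d1$death)
  o2 <- order(d2$dim, d2$birth, d2$death)
  expect_equal(d2$birth[o2], d1$birth[o1] + 13.5)
  expect_equal(d2$death[o2], d1$death[o1] + 13.5)
})

test_that("log scaling transforms values, keeps positions, guards positivity", {
  f <- matrix(exp(2), 3, 3); f[2, 2] <- exp(1)
  d <- compute_persistence(f)
  dl <- log_scale_diagram(d)
  expect_equal(dl$birth, log(d$birth))
  expect_equal(dl$death, log(d$death))
  expect_equal(dl$death_row, d$death_row)
  expect_true(attr(dl, "log_scaled"))
  f2 <- matrix(c(2, -1, 2, 2), 2, 2)
  expect_error(log_scale_diagram(compute_persistence(f2)), "non-positive")
  # a (1, 1) value maps to (0, 0)
  expect_equal(log_scale_diagram(compute_persistence(matrix(1, 2, 2)))$birth, 0)
})

test_that("fields must be finite", {
  expect_error(compute_persistence(matrix(c(1, Inf, 2, 3), 2, 2)), "finite")
})
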