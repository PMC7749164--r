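# Independent brute-force oracles used by the test suite. These deliberately
# avoid the package's production code paths: components are counted by label
# propagation over masks, distances by exhaustive search, thresholds by
# exhaustive scan, and Betti numbers threshold by threshold.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# connected-component count of a logical mask by iterative minimum-label
# propagation (independent of the union-find in src/)
label_components <- function(mask, connectivity = 8) {
  if (!any(mask)) return(matrix(NA_real_, nrow(mask), ncol(mask)))
  dirs <- if (connectivity == 8) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else {
    list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  }
  lab <- matrix(seq_along(mask), nrow(mask))
  lab[!mask] <- NA_real_
  repeat {
    new <- lab
    for (d in dirs) {
      s <- shift_mat(lab, d[1], d[2])
      new <- pmin(new, s, na.rm = TRUE)
    }
    new[!mask] <- NA_real_
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

count_components <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  length(unique(lab[!is.na(lab)]))
}

# bounded 4-connected components of the complement (the holes of `mask`):
# pad with a TRUE ring so everything reaching the frame joins one outer
# component, then discount it
count_holes_oracle <- function(mask) {
  bg <- !mask
  padded <- rbind(TRUE, cbind(TRUE, bg, TRUE), TRUE)
  lab <- label_components(padded, connectivity = 4)
  labs <- unique(lab[!is.na(lab)])
  outer_lab <- lab[1, 1]
  length(setdiff(labs, outer_lab))
}

# Euler characteristic of the 8-connectivity digital image of `mask`
# (triangulated: squares with all 4 vertices give 2 faces + 1 diagonal edge,
# 3 vertices give 1 face + 1 diagonal edge, a lone diagonal pair gives 1 edge)
euler_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  V <- sum(mask)
  E <- 0; F <- 0
  if (nr > 1) E <- E + sum(mask[-nr, , drop = FALSE] & mask[-1, , drop = FALSE])
  if (nc > 1) E <- E + sum(mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE])
  if (nr > 1 && nc > 1) {
    a <- mask[-nr, -nc, drop = FALSE]; b <- mask[-nr, -1, drop = FALSE]
    c <- mask[-1, -nc, drop = FALSE]; d <- mask[-1, -1, drop = FALSE]
    s <- a + b + c + d
    E <- E + sum(s == 4) + sum(s == 3) +
      sum(s == 2 & ((a & d) | (b & c)))
    F <- F + 2 * sum(s == 4) + sum(s == 3)
  }
  V - E + F
}

# Betti numbers of every distinct superlevel set, by direct counting
betti_sweep_oracle <- function(field) {
  ts <- sort(unique(as.vector(field)), decreasing = TRUE)
  data.frame(
    t = ts,
    b0 = vapply(ts, function(t) count_components(field >= t, 8), numeric(1)),
    b1 = vapply(ts, function(t) count_holes_oracle(field >= t), numeric(1))
  )
}

# Betti numbers implied by a persistence diagram: a pair is alive at
# threshold t when death < t <= birth; essential classes live down to the
# minimum (death sentinel), so they are alive whenever t <= birth
betti_from_diagram <- function(diagram, t) {
  alive <- ifelse(diagram$essential, t <= diagram$birth,
                  diagram$death < t & t <= diagram$birth)
  c(b0 = sum(alive & diagram$dim == 0), b1 = sum(alive & diagram$dim == 1))
}

# exhaustive Manhattan signed distance (O(n^2), small images only)
signed_distance_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  coords <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  white <- coords[as.vector(mask) == 1, , drop = FALSE]
  black <- coords[as.vector(mask) == 0, , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(coords))) {
    p <- coords[i, ]
    opp <- if (mask[p[1], p[2]] == 1) black else white
    d <- min(abs(opp[, 1] - p[1]) + abs(opp[, 2] - p[2]))
    out[p[1], p[2]] <- if (mask[p[1], p[2]] == 1) d else -d
  }
  out
}

# exhaustive Otsu: scan all 256 thresholds, maximize between-class variance
otsu_oracle <- function(values) {
  v <- as.vector(round(values))
  n <- length(v)
  best_t <- 0; best_s <- -1
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    s <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  if (best_s <= 0) best_t <- v[1]
  best_t
}

# exhaustive kNN distance: sort all point distances per query node
knn_field_oracle <- function(mask, k, spacing) {
  white <- which(mask == 1, arr.ind = TRUE)
  rows <- seq(1, nrow(mask), by = spacing)
  cols <- seq(1, ncol(mask), by = spacing)
  out <- matrix(NA_real_, length(rows), length(cols))
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    d <- sort(sqrt((white[, 1] - rows[i])^2 + (white[, 2] - cols[j])^2))
    out[i, j] <- d[k]
  }
  r_k <- out
  pos <- r_k[r_k > 0]
  r_k[r_k == 0] <- if (length(pos)) min(pos) else 1
  k / (nrow(white) * pi * r_k^2)
}

# feasibility of a bottleneck matching within eps between two (birth, death)
# point sets, diagonal projections allowed; simple augmenting-path matching
bottleneck_leq <- function(p1, p2, eps) {
  n <- nrow(p1); m <- nrow(p2)
  if (n == 0 && m == 0) return(TRUE)
  # left nodes: points of p1 then m diagonal slots; right: p2 then n slots
  nl <- n + m; nr2 <- m + n
  adj <- matrix(FALSE, nl, nr2)
  if (n && m) {
    for (i in seq_len(n)) for (j in seq_len(m)) {
      adj[i, j] <- max(abs(p1[i, ] - p2[j, ])) <= eps + 1e-9
    }
  }
  for (i in seq_len(n)) {           # p1 point -> its own diagonal slot
    adj[i, m + i] <- abs(p1[i, 1] - p1[i, 2]) / 2 <= eps + 1e-9
  }
  for (j in seq_len(m)) {           # diagonal slot -> p2 point
    adj[n + j, j] <- abs(p2[j, 1] - p2[j, 2]) / 2 <= eps + 1e-9
  }
  if (n && m) adj[(n + 1):nl, (m + 1):nr2] <- TRUE  # diagonal <-> diagonal
  match_r <- rep(0L, nr2)
  for (u in seq_len(nl)) {
    seen <- rep(FALSE, nr2)
    dfs <- function(a) {
      for (v in which(adj[a, ])) {
        if (!seen[v]) {
          seen[v] <<- TRUE
          if (match_r[v] == 0L || dfs(match_r[v])) {
            match_r[v] <<- a
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (!dfs(u)) return(FALSE)
  }
  TRUE
}

# numeric-integration oracle for the persistence-image mass of one point
pi_mass_numeric <- function(mid, life, rng, sigma, weight_max, n_grid = 2000) {
  xs <- seq(rng$mid[1], rng$mid[2], length.out = n_grid)
  ys <- seq(rng$life[1], rng$life[2], length.out = n_grid)
  dx <- diff(xs[1:2]); dy <- diff(ys[1:2])
  w <- min(max(life / weight_max, 0), 1)
  gx <- stats::dnorm(xs, mid, sigma)
  gy <- stats::dnorm(ys, life, sigma)
  w * sum(gx) * dx * sum(gy) * dy
}

# random integer-valued test field
random_field <- function(nr, nc, n_levels = 6) {
  matrix(sample.int(n_levels, nr * nc, replace = TRUE), nr, nc)
}

# random binary mask with both colours present
random_mask <- function(nr, nc, p = 0.5) {
  m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
  if (all(m == 1)) m[1, 1] <- 0
  if (all(m == 0)) m[1, 1] <- 1
  m
}
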