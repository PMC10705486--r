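# Fixtures and independent oracles used across the suite. Oracles are
# deliberately naive re-derivations (brute force, recursion, Monte Carlo)
# kept separate from the implementation paths they check.

# One dome, optionally noisy, at a fractional center so rasterisation is
# not pixel-aligned.
make_dome_scene <- function(a = 40, b = 40, h = 80, center = c(80.37, 60.22),
                            rows = 120, cols = 160, H = 1000, sigma = 0,
                            missing = 0, seed = 1, orientation = 0, ...) {
  generate_depth_scene(scene_spec(
    rows, cols, ground_distance = H,
    birds = list(bird_spec(center, a, b, h, orientation)),
    depth_noise_sigma = sigma, missing_pixel_rate = missing, seed = seed, ...
  ))
}

# Smooth random blob: union of a few overlapping discs (no 1-px spurs).
random_blob_mask <- function(seed, rows = 60, cols = 60) {
  set.seed(seed)
  m <- matrix(FALSE, rows, cols)
  g <- expand.grid(y = seq_len(rows), x = seq_len(cols))
  s <- min(rows, cols)
  for (k in seq_len(sample(2:4, 1))) {
    cx <- runif(1, 0.3 * cols, 0.7 * cols)
    cy <- runif(1, 0.3 * rows, 0.7 * rows)
    r <- runif(1, 0.10 * s, 0.22 * s)
    m[(g$x - cx)^2 + (g$y - cy)^2 < r^2] <- TRUE
  }
  m
}

# Fan-triangulation area of a star-shaped polygon about its centroid.
fan_area <- function(p) {
  c0 <- colMeans(p)
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    u <- p[i, ] - c0
    v <- p[j, ] - c0
    s <- s + (u[1] * v[2] - u[2] * v[1]) / 2
  }
  abs(s)
}

# Straightforward recursive Douglas-Peucker on an open chain.
dp_recursive <- function(p, eps) {
  n <- nrow(p)
  if (n <= 2L) return(p)
  a <- p[1L, ]; b <- p[n, ]
  A <- b[2] - a[2]; B <- a[1] - b[1]; C <- -(A * a[1] + B * a[2])
  nrm <- sqrt(A^2 + B^2)
  d <- if (nrm < 1e-12) {
    sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2)
  } else {
    abs(A * p[, 1] + B * p[, 2] + C) / nrm
  }
  d[c(1L, n)] <- 0
  k <- which.max(d)
  if (d[k] > eps) {
    left <- dp_recursive(p[1:k, , drop = FALSE], eps)
    right <- dp_recursive(p[k:n, , drop = FALSE], eps)
    rbind(left, right[-1L, , drop = FALSE])
  } else {
    p[c(1L, n), , drop = FALSE]
  }
}

# Closed-polygon reference: same anchor policy as approx_contour.
dp_reference_closed <- function(p, eps) {
  d0 <- (p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2
  i1 <- which.max(d0)
  c1 <- dp_recursive(p[1:i1, , drop = FALSE], eps)
  c2 <- dp_recursive(p[c(i1:nrow(p), 1L), , drop = FALSE], eps)
  rbind(c1, c2[-c(1L, nrow(c2)), , drop = FALSE])
}

# Exhaustive convexity-defect search: for every hull edge, maximise the
# point-line distance over every contour vertex strictly between its
# endpoints in contour order.
defects_bruteforce <- function(poly, hull) {
  n <- nrow(poly)
  hidx <- vapply(seq_len(nrow(hull)), function(i) {
    which(abs(poly[, 1] - hull[i, 1]) < 1e-9 &
          abs(poly[, 2] - hull[i, 2]) < 1e-9)[1L]
  }, integer(1))
  hidx <- sort(hidx)
  depths <- numeric(0)
  for (i in seq_along(hidx)) {
    i1 <- hidx[i]
    i2 <- if (i < length(hidx)) hidx[i + 1L] else hidx[1L]
    between <- if (i < length(hidx)) {
      if (i2 - i1 >= 2L) (i1 + 1L):(i2 - 1L) else integer(0)
    } else {
      c(if (i1 < n) (i1 + 1L):n else integer(0),
        if (i2 > 1L) 1L:(i2 - 1L) else integer(0))
    }
    if (length(between) == 0L) next
    a <- poly[i1, ]; b <- poly[i2, ]
    A <- b[2] - a[2]; B <- a[1] - b[1]; C <- -(A * a[1] + B * a[2])
    d <- max(abs(A * poly[between, 1] + B * poly[between, 2] + C) / sqrt(A^2 + B^2))
    depths <- c(depths, d)
  }
  depths
}

# Exhaustive best stump under squared loss: every feature, every midpoint
# of consecutive distinct sorted values.
best_stump_bruteforce <- function(X, r, min_cnt = 1L) {
  n <- nrow(X)
  best <- list(gain = -Inf, feature = NA, threshold = NA)
  sse <- function(v) sum((v - mean(v))^2)
  for (j in seq_len(ncol(X))) {
    ux <- sort(unique(X[, j]))
    if (length(ux) < 2L) next
    for (t in (ux[-1L] + ux[-length(ux)]) / 2) {
      l <- r[X[, j] <= t]; rr <- r[X[, j] > t]
      if (length(l) < min_cnt || length(rr) < min_cnt) next
      gain <- sse(r) - sse(l) - sse(rr)
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = j, threshold = t)
      }
    }
  }
  best
}

# Hand-rolled residual boosting with depth-1 stumps and shrinkage.
boost_stumps_reference <- function(X, y, K, rho) {
  f <- rep(mean(y), length(y))
  for (k in seq_len(K)) {
    r <- y - f
    sp <- best_stump_bruteforce(X, r)
    left <- X[, sp$feature] <= sp$threshold
    pred <- ifelse(left, mean(r[left]), mean(r[!left]))
    f <- f + rho * pred
  }
  f
}
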