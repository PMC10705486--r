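test_that("degenerate masks are rejected with a clear message", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_error(extract_contour(m), "at least 3 px")
  m2 <- matrix(FALSE, 5, 8); m2[3, 2:7] <- TRUE   # 1-px-wide line
  expect_error(extract_contour(m2), "degenerate|at least 3 px")
  expect_error(extract_contour(matrix(FALSE, 4, 4)), "empty")
})

test_that("a filled 10x10 square reduces to its 4 corners with perimeter 36", {
  m <- matrix(FALSE, 20, 20); m[5:14, 6:15] <- TRUE
  ct <- extract_contour(m)
  expect_equal(nrow(ct$vertices), 4)
  expect_equal(ct$perimeter, 36)
  expect_equal(as.numeric(polygon_area(ct)), 81)
  expect_equal(attr(polygon_area(ct$vertices), "orientation"), "ccw")
  expect_setequal(ct$vertices[, 1], c(6, 15))
  expect_setequal(ct$vertices[, 2], c(5, 14))
})

test_that("contour area approximates pixel count to within one perimeter", {
  for (seed in 1:8) {
    m <- random_blob_mask(seed)
    ct <- extract_contour(m)
    npx <- sum(broilerwt:::label_components(m, 8) ==
                 which.max(tabulate(broilerwt:::label_components(m, 8))))
    expect_lt(abs(as.numeric(polygon_area(ct)) - npx), ct$perimeter)
  }
})

test_that("traced boundary pixels agree with an independent tracer", {
  for (seed in c(2, 5)) {
    m <- random_blob_mask(seed)
    lab <- broilerwt:::label_components(m, 8)
    m <- lab == which.max(tabulate(lab[lab > 0]))
    ct <- extract_contour(m)
    oc <- EBImage::ocontour(EBImage::Image(t(m) * 1))[[1]]
    ours <- paste(ct$pixels[, 1], ct$pixels[, 2])
    ref <- paste(oc[, 1] + 1L, oc[, 2] + 1L)
    expect_setequal(ours, ref)
  }
})

test_that("shoelace area matches hand values and a fan-triangulation oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(as.numeric(polygon_area(sq)), 1)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(as.numeric(polygon_area(tri)), 6)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "3 vertices")
  set.seed(31)
  for (k in 1:10) {
    ang <- sort(runif(12, 0, 2 * pi))
    rad <- runif(12, 2, 10)
    poly <- cbind(rad * cos(ang), rad * sin(ang))  # star-shaped about origin
    expect_equal(as.numeric(polygon_area(poly)), fan_area(poly), tolerance = 1e-9)
  }
})

test_that("convex hull drops interior and collinear points and is a fixed point", {
  pts <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10),
               c(5, 5), c(3, 7), c(5, 0), c(10, 4))
  h <- convex_hull_poly(pts)
  expect_equal(nrow(h), 4)
  expect_setequal(paste(h[, 1], h[, 2]), c("0 0", "10 0", "10 10", "0 10"))
  expect_equal(convex_hull_poly(h), h, ignore_attr = TRUE)
  expect_error(convex_hull_poly(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))),
               "collinear")
})

test_that("hull area dominates every inscribed triangle of the point set", {
  set.seed(17)
  pts <- cbind(runif(60, 0, 50), runif(60, 0, 50))
  h <- convex_hull_poly(pts)
  ha <- hull_area(h)
  combs <- utils::combn(60, 3)
  tri_area <- function(i) {
    p <- pts[i, ]
    abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
        (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
  }
  areas <- apply(combs, 2, tri_area)
  expect_gte(ha, max(areas))
})

test_that("Douglas-Peucker collapses collinear midpoints and respects epsilon = 0", {
  sq <- rbind(c(0, 0), c(5, 0), c(10, 0), c(10, 5), c(10, 10),
              c(5, 10), c(0, 10), c(0, 5))
  got <- approx_contour(sq, epsilon = 1)
  expect_equal(nrow(got), 4)
  expect_setequal(paste(got[, 1], got[, 2]),
                  c("0 0", "10 0", "10 10", "0 10"))
  expect_identical(approx_contour(sq, epsilon = 0), sq)
  expect_error(approx_contour(sq, epsilon = -1), ">= 0")
})

test_that("Douglas-Peucker agrees with a recursive reference on jittered polygons", {
  set.seed(5)
  for (k in 1:6) {
    ang <- seq(0, 2 * pi, length.out = 101)[-101]
    rad <- 30 + runif(100, -2, 2)
    poly <- cbind(50 + rad * cos(ang), 50 + rad * sin(ang))
    for (eps in c(0.5, 1.5, 4)) {
      expect_equal(approx_contour(poly, eps), dp_reference_closed(poly, eps))
    }
  }
})

test_that("convex contours have no defects; a notch is measured exactly", {
  hexa <- rbind(c(2, 0), c(4, 0), c(6, 2), c(4, 4), c(2, 4), c(0, 2))
  expect_length(convexity_defects(hexa, convex_hull_poly(hexa)), 0)
  expect_equal(defect_sum(list()), 0)
  expect_equal(defect_max(list()), 0)
  # square with the bottom edge dented to (5, 5): point-line distance 5
  notched <- rbind(c(0, 0), c(5, 5), c(10, 0), c(10, 10), c(0, 10))
  defs <- convexity_defects(notched, convex_hull_poly(notched))
  expect_length(defs, 1)
  expect_equal(defs[[1]]$depth, 5)
  expect_equal(defs[[1]]$point, c(5, 5))
  expect_equal(defect_sum(defs), defect_max(defs))  # single defect
})

test_that("defect sum and max equal an exhaustive edge-by-vertex search", {
  set.seed(23)
  for (k in 1:6) {
    ang <- seq(0, 2 * pi, length.out = 17)[-17]
    rad <- ifelse(seq_along(ang) %% 2 == 0, 10, runif(16, 4, 9)[seq_along(ang)])
    star <- cbind(20 + rad * cos(ang), 20 + rad * sin(ang))
    hull <- convex_hull_poly(star)
    defs <- convexity_defects(star, hull)
    ref <- defects_bruteforce(star, hull)
    expect_equal(defect_sum(defs), sum(ref), tolerance = 1e-9)
    expect_equal(defect_max(defs), max(ref), tolerance = 1e-9)
    expect_gte(defect_sum(defs), defect_max(defs))
    expect_gte(defect_max(defs), 0)
  }
})

test_that("defects demand a hull that came from the same contour", {
  notched <- rbind(c(0, 0), c(5, 5), c(10, 0), c(10, 10), c(0, 10))
  alien <- rbind(c(-1, -1), c(20, -1), c(20, 20), c(-1, 20))
  expect_error(convexity_defects(notched, alien), "derived from this contour")
})
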