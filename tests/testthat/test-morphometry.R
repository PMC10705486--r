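disc_mask <- function(r, pad = 5) {
  n <- 2 * (r + pad) + 1
  g <- coordgrid <- expand.grid(y = 1:n, x = 1:n)
  m <- matrix((g$x - (r + pad + 1))^2 + (g$y - (r + pad + 1))^2 < r^2, n, n)
  m
}

ellipse_mask <- function(a, b, angle = 0, pad = 5) {
  n <- 2 * (max(a, b) + pad) + 1
  c0 <- max(a, b) + pad + 1
  g <- expand.grid(y = 1:n, x = 1:n)
  dx <- g$x - c0; dy <- g$y - c0
  u <- (cos(angle) * dx + sin(angle) * dy) / a
  v <- (-sin(angle) * dx + cos(angle) * dy) / b
  matrix(u^2 + v^2 < 1, n, n)
}

test_that("moment ellipse of a disc is a circle of the right size", {
  fe <- fit_ellipse(disc_mask(30))
  expect_lt(fe$eccentricity, 0.02)
  expect_lt(abs(fe$major - 60) / 60, 0.02)
  expect_lt(abs(fe$minor - 60) / 60, 0.02)
})

test_that("moment ellipse recovers the axis ratio of a filled ellipse", {
  fe <- fit_ellipse(ellipse_mask(40, 20))
  expect_equal(fe$eccentricity, sqrt(1 - 0.25), tolerance = 0.02)
  expect_lt(abs(fe$major - 80) / 80, 0.02)
  expect_lt(abs(fe$minor - 40) / 40, 0.02)
})

test_that("moment ellipse axes are invariant to rotation", {
  base <- fit_ellipse(ellipse_mask(35, 18, 0))
  for (ang in c(0.3, 0.9, 1.4, 2.2)) {
    fe <- fit_ellipse(ellipse_mask(35, 18, ang))
    expect_lt(abs(fe$major - base$major) / base$major, 0.02)
    expect_lt(abs(fe$minor - base$minor) / base$minor, 0.02)
  }
})

test_that("ellipse fitting rejects degenerate masks", {
  m <- matrix(FALSE, 9, 9); m[4, 2:8] <- TRUE   # zero variance across rows
  expect_error(fit_ellipse(m), "degenerate")
  expect_error(fit_ellipse(disc_mask(1)), "at least 5")
})

test_that("box ratio is exact for rectangles and triangles and bounded by 1", {
  rect <- rbind(c(2, 3), c(12, 3), c(12, 8), c(2, 8))
  expect_equal(box_features(rect)$area_to_box_ratio, 1)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(box_features(tri)$area_to_box_ratio, 0.5)
  for (seed in 1:8) {
    ct <- extract_contour(random_blob_mask(seed))
    expect_lte(box_features(ct)$area_to_box_ratio, 1 + 1e-9)
  }
})

test_that("min-area rectangle never exceeds the axis-aligned box", {
  for (seed in 1:5) {
    ct <- extract_contour(random_blob_mask(seed))
    bx <- box_features(ct)
    expect_lte(bx$min_rect$area, bx$width * bx$height + 1e-9)
  }
})

test_that("depth statistics match hand arithmetic and a two-pass oracle", {
  img <- matrix(900, 4, 4)
  m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
  ds <- depth_statistics(img, m)
  expect_equal(ds$max, 900); expect_equal(ds$min, 900)
  expect_equal(ds$range, 0); expect_equal(ds$sd, 0)
  expect_equal(ds$dist_min_to_avg, 0); expect_equal(ds$dist_max_to_avg, 0)

  img2 <- matrix(0, 2, 2); img2[] <- c(8, 9, 10, 13)
  ds2 <- depth_statistics(img2, matrix(TRUE, 2, 2))
  expect_equal(ds2$mean, 10); expect_equal(ds2$range, 5)
  expect_equal(ds2$sum, 40); expect_equal(ds2$sd, sqrt(3.5))

  set.seed(12)
  img3 <- matrix(runif(400, 500, 1000), 20, 20)
  m3 <- random_blob_mask(3, 20, 20)
  ds3 <- depth_statistics(img3, m3)
  d <- img3[m3]
  expect_equal(ds3$sd, sqrt(mean(d^2) - mean(d)^2), tolerance = 1e-9)

  expect_error(depth_statistics(matrix(0, 4, 4), m), "missing")
})

test_that("approximate volume reproduces direct arithmetic", {
  img <- matrix(20, 3, 3)
  m <- matrix(FALSE, 3, 3); m[1:2, 1:2] <- TRUE
  img[m] <- c(8, 8, 9, 10)
  # flat object: every masked depth equals the reference, area = pixel count
  flat <- matrix(10, 3, 3)
  expect_equal(approximate_volume(4, flat, m, NULL, reference = "mask"), 0)
  # Area 4, reference max 10, depths {8, 8, 9, 10}: 4 * 10 - 35 = 5
  expect_equal(approximate_volume(4, img, m, NULL, reference = "mask"), 5)
})

test_that("dome volume lands within 3% of the analytic half-ellipsoid", {
  cases <- list(
    list(a = 40, b = 40, h = 80, center = c(80.37, 60.22), orientation = 0),
    list(a = 45, b = 28, h = 110, center = c(84.61, 63.18), orientation = 0.7)
  )
  for (cs in cases) {
    sc <- make_dome_scene(a = cs$a, b = cs$b, h = cs$h, center = cs$center,
                          orientation = cs$orientation)
    fe <- extract_features(sc$depth, sc$masks[[1]])
    va <- analytic_halfellipsoid_volume(cs$a, cs$b, cs$h)
    expect_lt(abs(fe[["f17_approx_volume"]] - va) / va, 0.03)
  }
})

test_that("the feature vector has the 25 named fields and is translation invariant", {
  sc <- make_dome_scene(seed = 8)
  fe <- extract_features(sc$depth, sc$masks[[1]])
  expect_length(fe, 25)
  expect_identical(names(fe), feature_names())

  # translate depth and mask by (dy, dx) = (7, 5)
  v <- sc$depth$values; m <- sc$masks[[1]]$mask
  v2 <- matrix(sc$depth$ground_distance, nrow(v), ncol(v))
  m2 <- matrix(FALSE, nrow(v), ncol(v))
  v2[8:nrow(v), 6:ncol(v)] <- v[1:(nrow(v) - 7), 1:(ncol(v) - 5)]
  m2[8:nrow(v), 6:ncol(v)] <- m[1:(nrow(v) - 7), 1:(ncol(v) - 5)]
  fe2 <- extract_features(depth_image(v2, sc$depth$ground_distance), m2)
  expect_equal(fe2, fe, tolerance = 1e-12)
})

test_that("area and perimeter follow their scaling laws", {
  small <- make_dome_scene(a = 40, b = 28, h = 80, center = c(160.37, 120.22),
                           rows = 240, cols = 320)
  big <- make_dome_scene(a = 80, b = 56, h = 80, center = c(160.37, 120.22),
                         rows = 240, cols = 320)
  fs <- extract_features(small$depth, small$masks[[1]])
  fb <- extract_features(big$depth, big$masks[[1]])
  expect_lt(abs(fb[["f01_projected_area"]] / fs[["f01_projected_area"]] - 4) / 4, 0.02)
  expect_lt(abs(fb[["f02_contour_perimeter"]] / fs[["f02_contour_perimeter"]] - 2) / 2, 0.02)
})

test_that("feature invariants hold across 200 random synthetic scenes", {
  n_bad <- 0
  for (seed in 1:200) {
    sc <- generate_depth_scene(random_scene_spec(
      seed + 5000, rows = 150, cols = 200, n_birds = 1,
      depth_noise_sigma = c(0, 2, 4)[1 + seed %% 3],
      missing_pixel_rate = c(0, 0.005)[1 + seed %% 2]))
    fe <- extract_features(sc$depth, sc$masks[[1]])
    ok <- all(
      fe[["f01_projected_area"]] <= fe[["f05_hull_area"]] + 1e-9,
      fe[["f02_contour_perimeter"]] >= fe[["f09_hull_perimeter"]] - 1e-9,
      fe[["f11_approx_contour_perimeter"]] <= fe[["f02_contour_perimeter"]] + 1e-9,
      fe[["f12_area_to_box_ratio"]] > 0, fe[["f12_area_to_box_ratio"]] <= 1 + 1e-9,
      fe[["f13_area_to_hull_ratio"]] > 0, fe[["f13_area_to_hull_ratio"]] <= 1 + 1e-9,
      fe[["f08_eccentricity"]] >= 0, fe[["f08_eccentricity"]] < 1,
      abs(fe[["f21_depth_range"]] - (fe[["f18_max_depth"]] - fe[["f19_min_depth"]])) < 1e-9,
      abs(fe[["f24_dist_min_to_avg_depth"]] - (fe[["f20_mean_depth"]] - fe[["f19_min_depth"]])) < 1e-9,
      abs(fe[["f25_dist_max_to_avg_depth"]] - (fe[["f18_max_depth"]] - fe[["f20_mean_depth"]])) < 1e-9,
      abs(fe[["f16_equiv_diameter"]] - sqrt(4 * fe[["f01_projected_area"]] / pi)) < 1e-9,
      abs(pi * (fe[["f16_equiv_diameter"]] / 2)^2 - fe[["f01_projected_area"]]) < 1e-9,
      fe[["f15_sum_convexity_defects"]] >= fe[["f14_max_convexity_defect"]] - 1e-12,
      fe[["f14_max_convexity_defect"]] >= 0,
      fe[["f17_approx_volume"]] > 0,
      all(is.finite(fe))
    )
    if (!ok) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})
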