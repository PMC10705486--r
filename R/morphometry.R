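#' Names of the 25 morphometric features
#'
#' The fixed identifiers and order of the artificial feature vector:
#' 2D shape features from the instance mask and its contour (f01-f16) and
#' 3D features from the masked depth values (f17-f25). Units: px and px^2
#' for 2D features, mm for depth features, px^2 mm for the approximate
#' volume.
#'
#' @return character vector of length 25.
#' @export
feature_names <- function() {
  c("f01_projected_area",        # px^2, Green's-formula contour area
    "f02_contour_perimeter",     # px
    "f03_width",                 # px, bounding-box width
    "f04_height",                # px, bounding-box height
    "f05_hull_area",             # px^2
    "f06_minor_axis_length",     # px, fitted ellipse
    "f07_major_axis_length",     # px, fitted ellipse
    "f08_eccentricity",          # unitless, in [0, 1)
    "f09_hull_perimeter",        # px
    "f10_approx_contour_area",   # px^2, Douglas-Peucker contour
    "f11_approx_contour_perimeter", # px
    "f12_area_to_box_ratio",     # unitless, in (0, 1]
    "f13_area_to_hull_ratio",    # unitless, in (0, 1]
    "f14_max_convexity_defect",  # px
    "f15_sum_convexity_defects", # px
    "f16_equiv_diameter",        # px, circle with area f01
    "f17_approx_volume",         # px^2 mm
    "f18_max_depth",             # mm
    "f19_min_depth",             # mm
    "f20_mean_depth",            # mm
    "f21_depth_range",           # mm, f18 - f19
    "f22_depth_sd",              # mm, population sd
    "f23_depth_sum",             # mm
    "f24_dist_min_to_avg_depth", # mm, f20 - f19
    "f25_dist_max_to_avg_depth") # mm, f18 - f20
}

#' Fit an ellipse to a mask by second-order moments
#'
#' Axis lengths are computed from the eigenvalues of the population
#' covariance matrix of the mask's pixel coordinates: each full axis is
#' `4 * sqrt(eigenvalue)`, which reproduces the axes of an ideal filled
#' ellipse. Eccentricity is `sqrt(1 - (minor/major)^2)`.
#'
#' @param mask [instance_mask()] or logical matrix with at least 5 px.
#' @return list with `major`, `minor` (full axis lengths, px), `eccentricity`
#'   and `angle` (orientation of the major axis, radians).
#' @export
fit_ellipse <- function(mask) {
  m <- as_mask_matrix(mask)
  px <- which(m)
  if (length(px) < 5L) stop("ellipse fitting needs at least 5 mask pixels", call. = FALSE)
  nr <- nrow(m)
  y <- ((px - 1L) %% nr) + 1L
  x <- ((px - 1L) %/% nr) + 1L
  n <- length(px)
  cx <- mean(x); cy <- mean(y)
  sxx <- sum((x - cx)^2) / n
  syy <- sum((y - cy)^2) / n
  sxy <- sum((x - cx) * (y - cy)) / n
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  if (ev$values[2] <= 1e-9) {
    stop("mask is degenerate (zero variance along one axis)", call. = FALSE)
  }
  major <- 4 * sqrt(ev$values[1])
  minor <- 4 * sqrt(ev$values[2])
  list(
    major = major, minor = minor,
    eccentricity = sqrt(1 - (minor / major)^2),
    angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  )
}

# Minimum-area enclosing rectangle by rotating calipers over hull edges.
min_area_rect <- function(hull) {
  h <- as_polygon(hull)
  n <- nrow(h)
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- h[j, ] - h[i, ]
    len <- sqrt(sum(d^2))
    if (len < 1e-12) next
    d <- d / len
    nv <- c(-d[2], d[1])
    pr1 <- h[, 1] * d[1] + h[, 2] * d[2]
    pr2 <- h[, 1] * nv[1] + h[, 2] * nv[2]
    w <- max(pr1) - min(pr1)
    ht <- max(pr2) - min(pr2)
    if (is.null(best) || w * ht < best$area) {
      best <- list(width = w, height = ht, area = w * ht,
                   angle = atan2(d[2], d[1]))
    }
  }
  best
}

#' Bounding-rectangle features of a contour
#'
#' The axis-aligned bounding rectangle supplies the animal's width and
#' height on the image grid and the ratio of contour area to rectangle
#' area; the minimum-area (rotated) rectangle is computed alongside as a
#' diagnostic.
#'
#' @param contour [extract_contour()] output or polygon matrix.
#' @return list with `width`, `height` (px), `area_to_box_ratio` and
#'   `min_rect` (list: width, height, area, angle).
#' @export
box_features <- function(contour) {
  p <- as_polygon(contour)
  w <- max(p[, 1]) - min(p[, 1])
  h <- max(p[, 2]) - min(p[, 2])
  area <- as.numeric(polygon_area(p))
  list(
    width = w, height = h,
    area_to_box_ratio = area / (w * h),
    min_rect = min_area_rect(convex_hull_poly(p))
  )
}

#' Depth statistics over a masked region
#'
#' Maximum, minimum, mean, range, population standard deviation and sum of
#' the non-missing depth values under the mask, plus the constructed
#' distances mean-to-min and max-to-mean.
#'
#' @param img [depth_image()] or numeric matrix (mm, 0 = missing).
#' @param mask [instance_mask()] or logical matrix.
#' @return named list: `max`, `min`, `mean`, `range`, `sd`, `sum`,
#'   `dist_min_to_avg`, `dist_max_to_avg` (all mm).
#' @export
depth_statistics <- function(img, mask) {
  vals <- as_depth_values(img)
  m <- as_mask_matrix(mask)
  if (!identical(dim(vals), dim(m))) stop("mask and image shapes differ", call. = FALSE)
  d <- vals[m]
  d <- d[d > 0]
  if (length(d) == 0L) stop("all masked depth values are missing", call. = FALSE)
  mu <- mean(d)
  list(
    max = max(d), min = min(d), mean = mu,
    range = max(d) - min(d),
    sd = sqrt(sum((d - mu)^2) / length(d)),
    sum = sum(d),
    dist_min_to_avg = mu - min(d),
    dist_max_to_avg = max(d) - mu
  )
}

#' Approximate dome volume carved into the ground plane
#'
#' The animal's back forms a valley in the depth image; its volume is the
#' volume of the cylinder over the projected region, with height equal to a
#' reference distance near the ground plane, minus the sum of masked depth
#' values: `projected_area * reference - sum(D_p)`.
#'
#' The reference distance can be the image's known camera-to-ground
#' distance (`"ground"`, the quantity the contour-edge maximum
#' approximates), the maximum depth over the contour's boundary pixels
#' (`"contour"`), or the maximum over all masked pixels (`"mask"`). On
#' rasterised scenes the boundary-pixel maximum systematically undershoots
#' the ground distance by an amount that depends on where pixel centers
#' fall relative to the footprint edge, and this shortfall is multiplied by
#' the full pixel count; `"ground"` is therefore the default whenever the
#' ground distance is known.
#'
#' @param projected_area base area of the cylinder, px^2. For a volume
#'   consistent with the per-pixel sum this should be the number of
#'   non-missing target pixels (what [extract_features()] passes); the
#'   contour-polygon area undercounts the pixel region by roughly half the
#'   boundary band.
#' @param img [depth_image()] or matrix (mm).
#' @param mask [instance_mask()] or logical matrix.
#' @param contour [extract_contour()] output for the same mask.
#' @param reference `"ground"`, `"contour"` or `"mask"`; defaults to
#'   `"ground"` when the image carries a ground distance, else `"contour"`.
#' @return volume in px^2 mm.
#' @export
approximate_volume <- function(projected_area, img, mask, contour,
                               reference = NULL) {
  vals <- as_depth_values(img)
  m <- as_mask_matrix(mask)
  if (is.null(reference)) {
    reference <- if (is_depth_image(img)) "ground" else "contour"
  }
  reference <- match.arg(reference, c("ground", "contour", "mask"))
  d <- vals[m]
  d <- d[d > 0]
  if (length(d) == 0L) stop("all masked depth values are missing", call. = FALSE)
  ref <- switch(reference,
    ground = {
      if (!is_depth_image(img)) stop("`reference = \"ground\"` needs a depth_image with ground_distance", call. = FALSE)
      img$ground_distance
    },
    contour = {
      if (missing(contour) || is.null(contour)) stop("contour is required for the contour reference", call. = FALSE)
      pix <- if (inherits(contour, "contour")) contour$pixels else as_polygon(contour)
      nr <- nrow(vals)
      dv <- vals[(pix[, 1] - 1L) * nr + pix[, 2]]
      dv <- dv[dv > 0]
      if (length(dv) == 0L) stop("all contour depth values are missing", call. = FALSE)
      max(dv)
    },
    mask = max(d)
  )
  projected_area * ref - sum(d)
}

#' Extract the 25 morphometric features of one instance
#'
#' Computes the full artificial feature vector from an instance mask and
#' its depth image: contour-derived shape features (area by Green's
#' formula, perimeters, convex hull, Douglas-Peucker approximate contour at
#' `epsilon` = 1% of the perimeter, convexity defects, bounding-box ratios,
#' fitted-ellipse axes and eccentricity, equivalent-circle diameter),
#' depth statistics, and the approximate dome volume. The head is not
#' removed: features describe the whole segmented animal.
#'
#' Convexity defects are measured on the approximate contour by default
#' (set `defects_on = "raw"` for the unsimplified boundary).
#'
#' @param img [depth_image()].
#' @param mask [instance_mask()] or logical matrix.
#' @param defects_on `"approx"` (default) or `"raw"`.
#' @param volume_reference passed to [approximate_volume()]; default uses
#'   the ground distance when known.
#' @return named numeric vector of length 25 (see [feature_names()]).
#' @export
extract_features <- function(img, mask, defects_on = c("approx", "raw"),
                             volume_reference = NULL) {
  defects_on <- match.arg(defects_on)
  m <- as_mask_matrix(mask)
  ct <- extract_contour(m)
  area <- as.numeric(polygon_area(ct$vertices))
  hull <- convex_hull_poly(ct$vertices)
  ap <- approx_contour(ct)
  defect_poly <- if (defects_on == "approx") ap else ct$vertices
  defects <- convexity_defects(defect_poly, convex_hull_poly(defect_poly))
  ell <- fit_ellipse(m)
  bx <- box_features(ct)
  ds <- depth_statistics(img, m)
  vals <- as_depth_values(img)
  m_px <- sum(m & vals > 0)
  vol <- approximate_volume(m_px, img, m, ct, reference = volume_reference)
  out <- c(
    area,
    ct$perimeter,
    bx$width,
    bx$height,
    hull_area(hull),
    ell$minor,
    ell$major,
    ell$eccentricity,
    hull_perimeter(hull),
    as.numeric(polygon_area(ap)),
    polygon_perimeter(ap, closed = TRUE),
    bx$area_to_box_ratio,
    area / hull_area(hull),
    defect_max(defects),
    defect_sum(defects),
    sqrt(4 * area / pi),
    vol,
    ds$max, ds$min, ds$mean, ds$range, ds$sd, ds$sum,
    ds$dist_min_to_avg, ds$dist_max_to_avg
  )
  names(out) <- feature_names()
  out
}

#' Extract features for every instance of a scene
#'
#' @param img [depth_image()].
#' @param masks list of [instance_mask()] objects (pairwise disjoint).
#' @param ... passed to [extract_features()].
#' @return data frame with `instance_id` and the 25 feature columns.
#' @export
extract_scene_features <- function(img, masks, ...) {
  masks <- validate_segmentation(masks, shape = dim(as_depth_values(img)))
  rows <- lapply(masks, function(mk) {
    as.data.frame(as.list(extract_features(img, mk, ...)))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), 25L), feature_names()))
  }
  cbind(instance_id = vapply(masks, `[[`, integer(1), "instance_id"), out)
}
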