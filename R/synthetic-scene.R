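#' Specify one synthetic bird
#'
#' A bird is modelled as a half-ellipsoid dome sitting on the ground plane:
#' an elliptical footprint with semi-axes `a`, `b` (pixels) rotated by
#' `orientation`, rising to `h` mm above the ground at its center. Seen from
#' a downward-looking depth camera this produces the characteristic
#' valley-shaped depth profile of a bird's back.
#'
#' @param center length-2 numeric, (x = column, y = row) of the dome center
#'   in pixel coordinates (need not be integer).
#' @param a,b footprint semi-axes in pixels, at least 3.
#' @param h dome height in mm (must be below the scene's ground distance).
#' @param orientation rotation of the `a` axis, radians, counter-clockwise
#'   in pixel coordinates.
#' @return an object of class `bird_spec`.
#' @export
bird_spec <- function(center, a, b, h, orientation = 0) {
  if (length(center) != 2L || !is.numeric(center)) {
    stop("`center` must be numeric (x, y)", call. = FALSE)
  }
  for (nm in c("a", "b", "h", "orientation")) stop_if_not_scalar_number(get(nm), nm)
  if (a < 3 || b < 3) stop("semi-axes `a` and `b` must be at least 3 px", call. = FALSE)
  if (h <= 0) stop("dome height `h` must be positive", call. = FALSE)
  structure(
    list(center = as.numeric(center), a = a, b = b, h = h,
         orientation = orientation),
    class = "bird_spec"
  )
}

#' Specify a synthetic depth scene
#'
#' Describes a flat ground plane at distance `ground_distance` from the
#' camera with zero or more half-ellipsoid birds on it, plus a simple sensor
#' model: additive Gaussian depth noise (mm, truncated at three standard
#' deviations) and a fraction of randomly missing pixels (encoded 0).
#' Weights are linked to true dome volume through the allometric model
#' `weight = weight_coef * volume * (1 + eps)`, `eps ~ N(0, weight_sigma_rel)`.
#'
#' @param rows,cols image size in pixels.
#' @param ground_distance camera-to-ground distance in mm.
#' @param birds list of [bird_spec()] objects.
#' @param depth_noise_sigma standard deviation of depth noise in mm.
#' @param missing_pixel_rate fraction of pixels dropped to 0, in `[0, 1)`.
#' @param weight_coef allometric coefficient, kg per px^2 mm of dome volume.
#' @param weight_sigma_rel relative sd of the weight noise, in `[0, 0.5)`.
#' @param seed integer seed; identical specs give bit-identical scenes.
#' @param disjoint if `TRUE` (default), overlapping bird footprints are an
#'   error.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(rows, cols, ground_distance = 1000, birds = list(),
                       depth_noise_sigma = 0, missing_pixel_rate = 0,
                       weight_coef = 5e-6, weight_sigma_rel = 0,
                       seed = 1L, disjoint = TRUE) {
  for (nm in c("rows", "cols", "ground_distance", "depth_noise_sigma",
               "missing_pixel_rate", "weight_coef", "weight_sigma_rel")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (rows < 1 || cols < 1) stop("image size must be positive", call. = FALSE)
  if (depth_noise_sigma < 0) stop("`depth_noise_sigma` must be >= 0", call. = FALSE)
  if (missing_pixel_rate < 0 || missing_pixel_rate >= 1) {
    stop("`missing_pixel_rate` must be in [0, 1)", call. = FALSE)
  }
  if (weight_sigma_rel < 0 || weight_sigma_rel >= 0.5) {
    stop("`weight_sigma_rel` must be in [0, 0.5)", call. = FALSE)
  }
  if (!all(vapply(birds, inherits, logical(1), "bird_spec"))) {
    stop("`birds` must be a list of bird_spec objects", call. = FALSE)
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         ground_distance = ground_distance, birds = birds,
         depth_noise_sigma = depth_noise_sigma,
         missing_pixel_rate = missing_pixel_rate,
         weight_coef = weight_coef, weight_sigma_rel = weight_sigma_rel,
         seed = as.integer(seed), disjoint = isTRUE(disjoint)),
    class = "scene_spec"
  )
}

#' Closed-form volume of a half-ellipsoid dome
#'
#' The dome with footprint semi-axes `a`, `b` (px) and height `h` (mm) has
#' volume `(2/3) * pi * a * b * h` (px^2 mm). This is the analytic oracle
#' against which the discrete approximate-volume feature is validated.
#'
#' @param a,b footprint semi-axes, px.
#' @param h dome height, mm.
#' @return dome volume in px^2 mm.
#' @export
analytic_halfellipsoid_volume <- function(a, b, h) {
  if (any(!is.finite(c(a, b, h))) || any(c(a, b, h) <= 0)) {
    stop("`a`, `b` and `h` must all be positive", call. = FALSE)
  }
  (2 / 3) * pi * a * b * h
}

#' Draw a body weight from the allometric volume model
#'
#' `weight = coef * volume * (1 + eps)` with `eps ~ Normal(0, sigma_rel)`;
#' non-positive draws are resampled so weights are strictly positive. Uses
#' the current RNG stream; seed with [set.seed()] (or rely on the scene
#' generator, which seeds deterministically).
#'
#' @param volume dome volume, px^2 mm (vectorised).
#' @param coef allometric coefficient, kg per px^2 mm.
#' @param sigma_rel relative noise sd, in `[0, 0.5)`.
#' @return weights in kg, same length as `volume`.
#' @export
assign_weight <- function(volume, coef, sigma_rel = 0) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("`volume` must be positive", call. = FALSE)
  }
  stop_if_not_scalar_number(coef, "coef")
  stop_if_not_scalar_number(sigma_rel, "sigma_rel")
  if (sigma_rel < 0 || sigma_rel >= 0.5) {
    stop("`sigma_rel` must be in [0, 0.5)", call. = FALSE)
  }
  w <- coef * volume * (1 + rnorm(length(volume), 0, sigma_rel))
  bad <- which(w <= 0)
  while (length(bad) > 0L) {
    w[bad] <- coef * volume[bad] * (1 + rnorm(length(bad), 0, sigma_rel))
    bad <- bad[w[bad] <= 0]
  }
  w
}

# Ellipse-normalised rotated coordinates of every pixel for one bird;
# returns the squared elliptic radius u^2 + v^2 as a rows x cols matrix.
bird_radius2 <- function(bird, rows, cols) {
  g <- coord_grid(rows, cols)
  dx <- g$x - bird$center[1]
  dy <- g$y - bird$center[2]
  co <- cos(bird$orientation)
  si <- sin(bird$orientation)
  u <- (co * dx + si * dy) / bird$a
  v <- (-si * dx + co * dy) / bird$b
  u^2 + v^2
}

#' Generate a synthetic depth scene with known ground truth
#'
#' Renders the ground plane at `ground_distance` mm and each bird as a
#' half-ellipsoid valley: inside the footprint the depth is
#' `H - h * sqrt(1 - u^2 - v^2)` where `(u, v)` are ellipse-normalised
#' rotated pixel coordinates. Instance masks are exactly the analytic
#' footprints (pixels with noiseless depth strictly below `H`). Additive
#' Gaussian noise (truncated at 3 sigma) and missing pixels (0) are applied
#' afterwards. All randomness derives from `spec$seed`, so identical specs
#' give bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `depth` (a [depth_image()]), `masks` (list
#'   of [instance_mask()] footprints, one per bird) and `truth` (data frame
#'   with `instance_id`, `volume_mm3`, `weight_kg`, carrying the weight
#'   model as attributes `weight_coef` and `weight_sigma_rel`).
#' @export
generate_depth_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  rows <- spec$rows; cols <- spec$cols; H <- spec$ground_distance
  depth <- matrix(H, rows, cols)
  covered <- matrix(FALSE, rows, cols)
  masks <- vector("list", length(spec$birds))
  vols <- numeric(length(spec$birds))
  for (i in seq_along(spec$birds)) {
    bird <- spec$birds[[i]]
    if (bird$h >= H) {
      stop(sprintf("bird %d: dome height (%g mm) must be below the ground distance (%g mm)",
                   i, bird$h, H), call. = FALSE)
    }
    r2 <- bird_radius2(bird, rows, cols)
    inside <- r2 < 1
    if (spec$disjoint && any(inside & covered)) {
      stop(sprintf("bird %d overlaps an earlier bird but the scene is flagged disjoint", i),
           call. = FALSE)
    }
    depth[inside] <- pmin(depth[inside], H - bird$h * sqrt(1 - r2[inside]))
    covered <- covered | inside
    masks[[i]] <- instance_mask(inside, instance_id = i)
    vols[i] <- analytic_halfellipsoid_volume(bird$a, bird$b, bird$h)
  }
  truth <- data.frame(instance_id = seq_along(spec$birds),
                      volume_mm3 = vols, weight_kg = numeric(length(vols)))
  with_seed(spec$seed, {
    if (spec$depth_noise_sigma > 0) {
      s <- spec$depth_noise_sigma
      noise <- clamp(matrix(rnorm(rows * cols, 0, s), rows, cols), -3 * s, 3 * s)
      depth <- pmax(depth + noise, 1)
    }
    # quantise to whole mm, the integer Z16 counts a real sensor emits;
    # covered pixels are floored so noiseless masked depth stays below H
    depth[covered] <- floor(depth[covered])
    depth[!covered] <- round(depth[!covered])
    if (spec$missing_pixel_rate > 0) {
      n_miss <- round(spec$missing_pixel_rate * rows * cols)
      if (n_miss > 0) depth[sample.int(rows * cols, n_miss)] <- 0
    }
    if (length(vols) > 0) {
      truth$weight_kg <- assign_weight(vols, spec$weight_coef, spec$weight_sigma_rel)
    }
  })
  attr(truth, "weight_coef") <- spec$weight_coef
  attr(truth, "weight_sigma_rel") <- spec$weight_sigma_rel
  list(
    depth = depth_image(depth, ground_distance = H,
                        tolerance = 3 * spec$depth_noise_sigma + 1),
    masks = masks,
    truth = truth
  )
}

#' Draw a random single- or multi-bird scene specification
#'
#' Emulates the acquisition conditions of a desk-scale broiler pen: a camera
#' about 1 m above the ground, 1-3 birds per frame, and a weight
#' distribution matching a 63-day-old bantam flock (truncated normal, mean
#' 1.599 kg, sd 0.277 kg, range 0.87-2.35 kg). A target weight is drawn
#' first and converted to dome dimensions through the allometric model, so
#' mask size, depth profile and weight are consistent: the target volume is
#' `w / weight_coef`, split into semi-axes and height using a random aspect
#' ratio `a/b` in 1.35-1.75 and height-to-width ratio `h/b` in 2.2-3.0.
#'
#' @param seed integer seed for this scene.
#' @param rows,cols image size, px.
#' @param n_birds number of birds (1-3 fit the default frame).
#' @param ground_distance camera height, mm.
#' @param depth_noise_sigma sensor noise sd, mm.
#' @param missing_pixel_rate fraction of dropped pixels.
#' @param weight_coef kg per px^2 mm.
#' @param weight_sigma_rel relative sd of weight noise.
#' @param weight_mean,weight_sd,weight_range weight distribution (kg).
#' @return a [scene_spec()].
#' @export
random_scene_spec <- function(seed, rows = 180, cols = 240, n_birds = 1,
                              ground_distance = 1000, depth_noise_sigma = 3,
                              missing_pixel_rate = 0.002, weight_coef = 5e-6,
                              weight_sigma_rel = 0,
                              weight_mean = 1.59875, weight_sd = 0.276945,
                              weight_range = c(0.87, 2.35)) {
  with_seed(seed, {
    birds <- list()
    tries <- 0L
    while (length(birds) < n_birds && tries < 400L) {
      tries <- tries + 1L
      w <- rnorm(1, weight_mean, weight_sd)
      if (w < weight_range[1] || w > weight_range[2]) next
      vol <- w / weight_coef
      q <- runif(1, 1.35, 1.75)  # a / b
      rr <- runif(1, 2.2, 3.0)   # h / b
      b <- (vol / ((2 / 3) * pi * q * rr))^(1 / 3)
      a <- q * b
      h <- rr * b
      if (a < 3 || b < 3 || h >= ground_distance) next
      margin <- a + 2
      if (2 * margin >= cols || 2 * margin >= rows) next
      cand <- bird_spec(
        center = c(runif(1, margin, cols - margin), runif(1, margin, rows - margin)),
        a = a, b = b, h = h, orientation = runif(1, 0, pi)
      )
      clear <- all(vapply(birds, function(bd) {
        sum((bd$center - cand$center)^2) > (max(bd$a, bd$b) + max(a, b) + 2)^2
      }, logical(1)))
      if (clear) birds <- c(birds, list(cand))
    }
    if (length(birds) < n_birds) {
      stop("could not place the requested number of non-overlapping birds", call. = FALSE)
    }
    scene_spec(rows, cols, ground_distance = ground_distance, birds = birds,
               depth_noise_sigma = depth_noise_sigma,
               missing_pixel_rate = missing_pixel_rate,
               weight_coef = weight_coef, weight_sigma_rel = weight_sigma_rel,
               seed = seed, disjoint = TRUE)
  })
}

#' Write a generated scene to disk
#'
#' Depth goes to a 16-bit PNG (mm), each mask to an 8-bit 0/255 PNG, and the
#' truth table to CSV (`instance_id`, `volume_mm3`, `weight_kg`).
#'
#' @param scene result of [generate_depth_scene()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(depth = file.path(dir, paste0(stem, "_depth.png")))
  write_depth_z16(scene$depth, paths[["depth"]])
  for (i in seq_along(scene$masks)) {
    p <- file.path(dir, sprintf("%s_mask_%02d.png", stem, i))
    write_mask_png(scene$masks[[i]], p)
    paths[[sprintf("mask_%02d", i)]] <- p
  }
  paths[["truth"]] <- file.path(dir, paste0(stem, "_truth.csv"))
  write.csv(scene$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
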