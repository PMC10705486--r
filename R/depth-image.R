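#' Depth-distance image
#'
#' A depth image is a matrix of camera-to-surface distances in millimetres,
#' as produced by a structured-light depth sensor mounted above the pen and
#' looking straight down. The value 0 marks missing (invalid) pixels, the
#' usual convention of 16-bit sensor output. `ground_distance` is the
#' camera-to-ground-plane distance in mm (about 1000 for a camera mounted
#' roughly 1 m above the floor); birds appear as "valleys" of values smaller
#' than `ground_distance`.
#'
#' @param values numeric matrix of distances in mm; 0 encodes missing pixels.
#' @param ground_distance camera-to-ground distance in mm.
#' @param source optional path the image was read from.
#' @param tolerance permitted excess of observed distances over
#'   `ground_distance` (mm), to accommodate sensor noise on ground pixels.
#' @return an object of class `depth_image`.
#' @export
depth_image <- function(values, ground_distance, source = NA_character_,
                        tolerance = 50) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  stop_if_not_scalar_number(ground_distance, "ground_distance")
  if (ground_distance <= 0) stop("`ground_distance` must be positive", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) {
    stop("depth values must be non-negative (0 = missing)", call. = FALSE)
  }
  finite_max <- suppressWarnings(max(values[values > 0]))
  if (is.finite(finite_max) && finite_max > ground_distance + tolerance) {
    stop(sprintf(
      "largest depth value (%.1f mm) exceeds ground_distance (%.1f mm) by more than %g mm",
      finite_max, ground_distance, tolerance
    ), call. = FALSE)
  }
  structure(
    list(values = values, ground_distance = ground_distance, source = source),
    class = "depth_image"
  )
}

#' @export
print.depth_image <- function(x, ...) {
  v <- x$values
  miss <- mean(v == 0)
  cat(sprintf(
    "<depth_image> %d x %d px, ground %g mm, %.1f%% missing, range [%g, %g] mm\n",
    nrow(v), ncol(v), x$ground_distance, 100 * miss,
    if (any(v > 0)) min(v[v > 0]) else NA, max(v)
  ))
  invisible(x)
}

#' @export
dim.depth_image <- function(x) dim(x$values)

is_depth_image <- function(x) inherits(x, "depth_image")

as_depth_values <- function(img) {
  if (is_depth_image(img)) img$values
  else if (is.matrix(img)) img
  else stop("expected a `depth_image` or a numeric matrix", call. = FALSE)
}
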