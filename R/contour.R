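# Contour geometry: boundary tracing, polygon area/perimeter, convex hull,
# Douglas-Peucker simplification, convexity defects.
#
# All polygons are n x 2 matrices of (x = column, y = row) pixel-center
# coordinates. "CCW" is defined by the shoelace integral: a CCW polygon has
# positive signed area under the convention used throughout the package.

as_polygon <- function(x) {
  if (inherits(x, "contour")) x$vertices
  else if (is.matrix(x) && ncol(x) == 2L) x
  else stop("expected a `contour` or an n x 2 coordinate matrix", call. = FALSE)
}

shoelace_signed <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1L)
  sum(p[, 1] * (p[i2, 2] - p[c(n, 1:(n - 1)), 2])) / 2
}

#' Polygon area by the shoelace (Green's formula) evaluation
#'
#' Evaluates the boundary integral of `x dy` around the closed contour,
#' which by Green's theorem equals the enclosed area. The absolute value is
#' returned; the traversal orientation is attached as attribute
#' `"orientation"` (`"ccw"` when the signed area is positive).
#'
#' @param poly closed simple polygon (n x 2 matrix or [extract_contour()]
#'   output); at least 3 vertices.
#' @return area in px^2 with attribute `orientation`.
#' @export
polygon_area <- function(poly) {
  p <- as_polygon(poly)
  if (nrow(p) < 3L) stop("a polygon needs at least 3 vertices", call. = FALSE)
  s <- shoelace_signed(p)
  structure(abs(s), orientation = if (s >= 0) "ccw" else "cw")
}

#' Perimeter of a polygon or open polyline
#'
#' @param poly n x 2 coordinate matrix or contour.
#' @param closed include the closing edge (default `TRUE`).
#' @return length in px.
#' @export
polygon_perimeter <- function(poly, closed = TRUE) {
  p <- as_polygon(poly)
  if (nrow(p) < 2L) return(0)
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  tot <- sum(d)
  if (closed) tot <- tot + sqrt(sum((p[1L, ] - p[nrow(p), ])^2))
  tot
}

# Remove vertices collinear with their neighbours in the direction of
# travel (straight-through only; reversals are kept).
merge_collinear <- function(p, tol = 1e-9) {
  repeat {
    n <- nrow(p)
    if (n < 4L) return(p)
    prv <- p[c(n, 1:(n - 1)), , drop = FALSE]
    nxt <- p[c(2:n, 1L), , drop = FALSE]
    u <- p - prv
    v <- nxt - p
    cross <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    dot <- u[, 1] * v[, 1] + u[, 2] * v[, 2]
    drop <- abs(cross) < tol & dot > 0
    if (!any(drop)) return(p)
    p <- p[!drop, , drop = FALSE]
  }
}

#' Trace the outer boundary of an instance mask
#'
#' Moore-neighbour boundary tracing of the largest connected component,
#' on pixel centers. Runs of collinear boundary pixels are merged, the
#' polygon is oriented CCW (positive shoelace area), and the full boundary
#' pixel chain is retained for depth lookups along the contour.
#'
#' The mask must have a two-dimensional extent: masks whose boundary
#' degenerates to a point or a line (e.g. a single pixel or a 1-px-wide
#' segment) are rejected.
#'
#' @param mask an [instance_mask()] or logical matrix; non-empty.
#' @return an object of class `contour`: list with `vertices` (n x 2, CCW),
#'   `perimeter` (px) and `pixels` (boundary pixel chain, m x 2).
#' @export
extract_contour <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  lab <- label_components(m, 8)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    m <- lab == which.max(sizes)
  }
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m)
  r <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  o <- order(r, cc)
  sr <- r[o[1L]]; sc <- cc[o[1L]]
  # clockwise Moore neighbourhood starting W: W NW N NE E SE S SW
  ndr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  ndc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  inside <- function(rr, cl) rr >= 1L && rr <= nr && cl >= 1L && cl <= nc
  path_r <- integer(0); path_c <- integer(0)
  cur_r <- sr; cur_c <- sc
  # backtrack direction: the neighbour index we entered from; start pointing W
  back <- 1L
  first_move <- NA_integer_
  maxit <- 8L * (length(fg) + 8L)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) stop("boundary tracing failed to terminate", call. = FALSE)
    path_r <- c(path_r, cur_r); path_c <- c(path_c, cur_c)
    found <- FALSE
    for (k in seq_len(8L)) {
      j <- ((back - 1L + k - 1L) %% 8L) + 1L  # clockwise from backtrack
      rr <- cur_r + ndr[j]; cl <- cur_c + ndc[j]
      if (inside(rr, cl) && m[rr, cl]) {
        # next backtrack points towards the previous pixel: opposite of j,
        # then advance one clockwise step so the search resumes just past it
        opp <- ((j - 1L + 4L) %% 8L) + 1L
        back <- (opp %% 8L) + 1L
        cur_r <- rr; cur_c <- cl
        found <- TRUE
        if (is.na(first_move)) first_move <- j
        break
      }
    }
    if (!found) break  # isolated pixel
    if (cur_r == sr && cur_c == sc) {
      # Jacob's criterion: stop when re-entering the start by the same move
      nxt <- NA_integer_
      for (k in seq_len(8L)) {
        j <- ((back - 1L + k - 1L) %% 8L) + 1L
        rr <- cur_r + ndr[j]; cl <- cur_c + ndc[j]
        if (inside(rr, cl) && m[rr, cl]) { nxt <- j; break }
      }
      if (is.na(nxt) || nxt == first_move) break
    }
  }
  pix <- cbind(x = path_c, y = path_r)
  verts <- merge_collinear(unique_consecutive(pix))
  if (nrow(verts) < 3L || abs(shoelace_signed(verts)) < 1e-9) {
    stop("mask boundary is degenerate: a contour needs at least 3 px of two-dimensional extent",
         call. = FALSE)
  }
  if (shoelace_signed(verts) < 0) verts <- verts[nrow(verts):1L, , drop = FALSE]
  structure(
    list(vertices = verts, perimeter = polygon_perimeter(verts, closed = TRUE),
         pixels = unique(pix)),
    class = "contour"
  )
}

unique_consecutive <- function(p) {
  if (nrow(p) < 2L) return(p)
  keep <- c(TRUE, rowSums(abs(p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])) > 0)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) > 1L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  p
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d vertices, perimeter %.2f px\n",
              nrow(x$vertices), x$perimeter))
  invisible(x)
}

#' Convex hull of a contour or point set
#'
#' Returns the hull polygon in CCW order with collinear vertices removed.
#'
#' @param x contour or n x 2 coordinate matrix with at least 3 non-collinear
#'   points.
#' @return hull polygon (k x 2 matrix, CCW).
#' @export
convex_hull_poly <- function(x) {
  p <- as_polygon(x)
  p <- unique(p)
  if (nrow(p) < 3L) stop("convex hull needs at least 3 distinct points", call. = FALSE)
  idx <- grDevices::chull(p[, 1], p[, 2])
  h <- p[idx, , drop = FALSE]
  if (nrow(h) < 3L || abs(shoelace_signed(h)) < 1e-12) {
    stop("all points are collinear; the convex hull is degenerate", call. = FALSE)
  }
  if (shoelace_signed(h) < 0) h <- h[nrow(h):1L, , drop = FALSE]
  merge_collinear(h)
}

#' Convex hull perimeter
#' @param hull hull polygon from [convex_hull_poly()].
#' @return length in px.
#' @export
hull_perimeter <- function(hull) polygon_perimeter(hull, closed = TRUE)

#' Convex hull area
#' @param hull hull polygon from [convex_hull_poly()].
#' @return area in px^2.
#' @export
hull_area <- function(hull) as.numeric(polygon_area(hull))

point_line_distance <- function(pts, p1, p2) {
  A <- p2[2] - p1[2]
  B <- p1[1] - p2[1]
  C <- -(A * p1[1] + B * p1[2])
  nrm <- sqrt(A^2 + B^2)
  if (nrm < 1e-12) {
    sqrt((pts[, 1] - p1[1])^2 + (pts[, 2] - p1[2])^2)
  } else {
    abs(A * pts[, 1] + B * pts[, 2] + C) / nrm
  }
}

dp_open <- function(p, eps) {
  n <- nrow(p)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- point_line_distance(p[mid, , drop = FALSE], p[i, ], p[j, ])
    k <- which.max(d)
    if (d[k] > eps) {
      km <- mid[k]
      keep[km] <- TRUE
      stack <- c(stack, list(c(i, km), c(km, j)))
    }
  }
  p[keep, , drop = FALSE]
}

#' Douglas-Peucker polygon simplification
#'
#' Simplifies a closed contour with the Douglas-Peucker algorithm. The
#' closed polygon is split at two anchors (the first vertex and the vertex
#' farthest from it), each open chain is simplified, and the chains are
#' rejoined. Every removed vertex lies within `epsilon` of the simplified
#' polyline. With `epsilon = 0` the input is returned unchanged.
#'
#' @param x contour or closed polygon matrix.
#' @param epsilon tolerance in px; default is 1% of the closed contour
#'   perimeter.
#' @return simplified polygon (k x 2 matrix, orientation preserved).
#' @export
approx_contour <- function(x, epsilon = NULL) {
  p <- as_polygon(x)
  if (is.null(epsilon)) epsilon <- 0.01 * polygon_perimeter(p, closed = TRUE)
  if (epsilon < 0) stop("`epsilon` must be >= 0", call. = FALSE)
  if (epsilon == 0 || nrow(p) <= 3L) return(p)
  d0 <- (p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2
  i1 <- which.max(d0)
  if (i1 == 1L) return(p)
  chain1 <- dp_open(p[1:i1, , drop = FALSE], epsilon)
  chain2 <- dp_open(p[c(i1:nrow(p), 1L), , drop = FALSE], epsilon)
  rbind(chain1, chain2[-c(1L, nrow(chain2)), , drop = FALSE])
}

#' Convexity defects of a contour against its hull
#'
#' For each hull edge subtending at least one off-hull contour vertex, the
#' defect is the contour vertex farthest from the edge's supporting line
#' `A x + B y + C = 0`; its depth is the point-line distance
#' `|A x + B y + C| / sqrt(A^2 + B^2)`. A convex contour has no defects.
#'
#' @param poly contour (or polygon matrix) the hull was derived from.
#' @param hull hull polygon from [convex_hull_poly()] of the same contour.
#' @return list of defects, each a list with `line` (A, B, C), `point`
#'   (x, y of the farthest vertex) and `depth` (px).
#' @export
convexity_defects <- function(poly, hull) {
  p <- as_polygon(poly)
  h <- as_polygon(hull)
  n <- nrow(p)
  hidx <- integer(nrow(h))
  for (i in seq_len(nrow(h))) {
    j <- which(abs(p[, 1] - h[i, 1]) < 1e-9 & abs(p[, 2] - h[i, 2]) < 1e-9)
    if (length(j) == 0L) {
      stop("hull vertex not found on the contour; was the hull derived from this contour?",
           call. = FALSE)
    }
    hidx[i] <- j[1L]
  }
  hidx <- sort(hidx)
  defects <- list()
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
    p1 <- p[i1, ]; p2 <- p[i2, ]
    A <- p2[2] - p1[2]
    B <- p1[1] - p2[1]
    C <- -(A * p1[1] + B * p1[2])
    d <- point_line_distance(p[between, , drop = FALSE], p1, p2)
    k <- which.max(d)
    defects[[length(defects) + 1L]] <- list(
      line = c(A = unname(A), B = unname(B), C = unname(C)),
      point = unname(p[between[k], ]),
      depth = d[k]
    )
  }
  defects
}

#' Sum of convexity-defect depths
#' @param defects output of [convexity_defects()].
#' @return total defect depth in px (0 for a convex contour).
#' @export
defect_sum <- function(defects) {
  if (length(defects) == 0L) return(0)
  sum(vapply(defects, `[[`, numeric(1), "depth"))
}

#' Maximum convexity-defect depth
#' @param defects output of [convexity_defects()].
#' @return largest defect depth in px (0 for a convex contour).
#' @export
defect_max <- function(defects) {
  if (length(defects) == 0L) return(0)
  max(vapply(defects, `[[`, numeric(1), "depth"))
}
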