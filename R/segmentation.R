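#' Instance mask
#'
#' A binary pixel mask singling out one animal in a depth image, together
#' with its instance id and pixel count. Masks belonging to one scene must
#' be pairwise disjoint.
#'
#' @param mask logical (or 0/1) matrix.
#' @param instance_id integer id of the instance.
#' @return an object of class `instance_mask`.
#' @export
instance_mask <- function(mask, instance_id = 1L) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  m <- mask != 0
  structure(
    list(mask = m, instance_id = as.integer(instance_id),
         pixel_count = sum(m)),
    class = "instance_mask"
  )
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask> id %d, %d px in a %d x %d image\n",
              x$instance_id, x$pixel_count, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

as_mask_matrix <- function(m) {
  if (inherits(m, "instance_mask")) m$mask
  else if (is.matrix(m)) m != 0
  else stop("expected an `instance_mask` or a matrix", call. = FALSE)
}

# Connected-component labelling by breadth-first flood fill.
# `connectivity` is 4 (edge neighbours) or 8 (edge + diagonal neighbours).
label_components <- function(bin, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8", call. = FALSE)
  nr <- nrow(bin); nc <- ncol(bin)
  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  nn <- if (connectivity == 4) 4L else 8L
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  queue <- integer(nr * nc)
  fg <- which(bin)
  for (s in fg) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    lab[s] <- nextlab
    queue[1L] <- s
    qh <- 1L; qt <- 1L
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      for (k in seq_len(nn)) {
        r <- pr + dr[k]; cc <- pc + dc[k]
        if (r < 1L || r > nr || cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + r
        if (bin[q] && lab[q] == 0L) {
          lab[q] <- nextlab
          qt <- qt + 1L
          queue[qt] <- q
        }
      }
    }
  }
  lab
}

#' Depth-threshold instance segmentation
#'
#' Deterministic fallback segmenter for clean scenes: every pixel whose
#' depth is more than `tau` mm above the ground plane (i.e. `d < H - tau`)
#' is foreground; foreground pixels are grouped into connected components,
#' components smaller than `min_area` are discarded, and the survivors are
#' returned ordered by decreasing pixel count (ties broken by the
#' top-left-most pixel). Missing pixels (0) are never foreground. An empty
#' scene yields an empty list, not an error.
#'
#' @param img a [depth_image()] (or numeric matrix, in which case `H` must
#'   be given).
#' @param H camera-to-ground distance in mm; defaults to the image's
#'   `ground_distance`.
#' @param tau depth margin in mm separating a bird's back from ground noise;
#'   the default 30 mm sits well above sensor noise of a few mm.
#' @param min_area smallest component kept, px.
#' @param connectivity 4 or 8 (default 8, which avoids splitting thin
#'   diagonal necks).
#' @return list of [instance_mask()] objects.
#' @export
threshold_segment <- function(img, H = NULL, tau = 30, min_area = 25,
                              connectivity = 8) {
  vals <- as_depth_values(img)
  if (is.null(H)) {
    if (!is_depth_image(img)) stop("`H` is required when `img` is a bare matrix", call. = FALSE)
    H <- img$ground_distance
  }
  stop_if_not_scalar_number(tau, "tau")
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  fg <- vals > 0 & vals < (H - tau)
  if (!any(fg)) return(list())
  lab <- label_components(fg, connectivity)
  k <- max(lab)
  comps <- lapply(seq_len(k), function(i) which(lab == i))
  sizes <- lengths(comps)
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L) return(list())
  nr <- nrow(vals)
  # top-left-most pixel: smallest row, then smallest column
  tiekey <- vapply(comps[keep], function(px) {
    r <- ((px - 1L) %% nr) + 1L
    cc <- ((px - 1L) %/% nr) + 1L
    rmin <- min(r)
    rmin * (ncol(vals) + 1) + min(cc[r == rmin])
  }, numeric(1))
  ord <- keep[order(-sizes[keep], tiekey)]
  out <- vector("list", length(ord))
  for (j in seq_along(ord)) {
    m <- matrix(FALSE, nr, ncol(vals))
    m[comps[[ord[j]]]] <- TRUE
    out[[j]] <- instance_mask(m, instance_id = j)
  }
  out
}

#' Intersection-over-union of two masks
#'
#' @param a,b [instance_mask()] objects or logical matrices of equal shape.
#' @return `|a and b| / |a or b|`. Two empty masks are an error (the ratio
#'   is undefined), as is a shape mismatch.
#' @export
mask_iou <- function(a, b) {
  ma <- as_mask_matrix(a); mb <- as_mask_matrix(b)
  if (!identical(dim(ma), dim(mb))) {
    stop("masks have different shapes", call. = FALSE)
  }
  uni <- sum(ma | mb)
  if (uni == 0L) stop("both masks are empty; IoU is undefined", call. = FALSE)
  sum(ma & mb) / uni
}

#' Validate the output of an instance segmenter
#'
#' Any segmentation backend (the built-in threshold segmenter, or an
#' external learned model such as a Mask R-CNN run outside R) is
#' interchangeable downstream as long as its output passes this check:
#' a list of `instance_mask` objects of the image's shape, pairwise
#' disjoint.
#'
#' @param masks list of [instance_mask()] objects.
#' @param shape expected `c(rows, cols)` (optional).
#' @return the masks, invisibly, with instance ids renumbered 1..k.
#' @export
validate_segmentation <- function(masks, shape = NULL) {
  if (!is.list(masks)) stop("segmenter output must be a list of masks", call. = FALSE)
  mats <- lapply(masks, as_mask_matrix)
  if (!is.null(shape)) {
    for (i in seq_along(mats)) {
      if (!identical(dim(mats[[i]]), as.integer(shape))) {
        stop(sprintf("mask %d has shape %s, expected %s", i,
                     paste(dim(mats[[i]]), collapse = "x"),
                     paste(shape, collapse = "x")), call. = FALSE)
      }
    }
  }
  if (length(mats) > 1L) {
    acc <- mats[[1L]]
    for (i in seq_along(mats)[-1L]) {
      if (any(acc & mats[[i]])) {
        stop(sprintf("segmenter output violates disjointness: mask %d overlaps an earlier mask", i),
             call. = FALSE)
      }
      acc <- acc | mats[[i]]
    }
  }
  out <- lapply(seq_along(mats), function(i) instance_mask(mats[[i]], instance_id = i))
  invisible(out)
}

#' Run a segmentation backend and validate its output
#'
#' @param segmenter a function `(depth_image) -> list of masks` honouring
#'   the contract checked by [validate_segmentation()].
#' @param img a [depth_image()].
#' @param ... passed to the segmenter.
#' @return validated list of [instance_mask()] objects.
#' @export
segment_with <- function(segmenter, img, ...) {
  stopifnot(is.function(segmenter))
  masks <- segmenter(img, ...)
  out <- validate_segmentation(masks, shape = dim(as_depth_values(img)))
  out
}
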