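#' Deterministic 2048-dimensional learned-feature stand-in
#'
#' Stands in for a CNN backbone (in the full pipeline, a ResNet-50 variant
#' fine-tuned for weight regression provides these activations). It fills
#' the same contract - one finite 2048-vector per instance - from pooled
#' multi-scale patch statistics of the masked depth region: the region's
#' height-above-reference map is resampled onto a 16 x 16 grid, pooled over
#' 1x1/2x2/4x4/8x8 blocks, combined with a handful of mask and depth
#' summary statistics, and projected to 2048 dimensions through a fixed
#' seeded Gaussian random projection. Deterministic given (input, seed).
#'
#' @param img [depth_image()].
#' @param mask [instance_mask()] or logical matrix; non-empty.
#' @param seed integer seed of the random projection (part of the embedding
#'   identity: two providers with different seeds give different, equally
#'   valid embeddings).
#' @return an `embedding`: numeric vector of length 2048 with attributes
#'   `provider_id` and `seed`.
#' @export
default_embed <- function(img, mask, seed = 1L) {
  vals <- as_depth_values(img)
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("instance region is empty", call. = FALSE)
  px <- which(m)
  nr <- nrow(m)
  rr <- range(((px - 1L) %% nr) + 1L)
  cr <- range(((px - 1L) %/% nr) + 1L)
  sub_v <- vals[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  sub_m <- m[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  d <- sub_v
  d[!sub_m | sub_v == 0] <- NA
  dmax <- max(d, na.rm = TRUE); dmin <- min(d, na.rm = TRUE)
  height <- (dmax - d) / max(dmax - dmin, 1)   # 0 at ground edge, 1 at back
  height[is.na(height)] <- 0
  g <- 16L
  ri <- pmin(pmax(ceiling(seq_len(g) / g * nrow(height)), 1L), nrow(height))
  ci <- pmin(pmax(ceiling(seq_len(g) / g * ncol(height)), 1L), ncol(height))
  grid <- height[ri, ci, drop = FALSE]
  pool <- function(k) {
    f <- g %/% k
    blocks <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      blocks[i, j] <- mean(grid[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
    }
    as.vector(blocks)
  }
  dm <- d[!is.na(d)]
  s <- c(
    unlist(lapply(c(1L, 2L, 4L, 8L), pool)),
    mean(sub_m),                        # fill fraction of the bounding box
    nrow(sub_m) / ncol(sub_m),          # aspect
    log1p(length(px)) / 12,
    (mean(dm) - dmin) / max(dmax - dmin, 1),
    stats::sd(grid[grid > 0]) %||% 0,
    mean(grid > 0.5)
  )
  s[!is.finite(s)] <- 0
  proj <- with_seed(seed, matrix(rnorm(2048L * length(s)), 2048L, length(s)))
  e <- as.numeric(proj %*% s) / sqrt(length(s))
  structure(e, provider_id = "patch-stats-rp", seed = as.integer(seed),
            class = "embedding")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Validate a learned-feature vector against the embedding contract
#'
#' Any external embedding provider (e.g. activations exported from a CNN
#' backbone run outside R) is accepted downstream if it emits exactly 2048
#' finite values per instance.
#'
#' @param e numeric vector.
#' @return the embedding, invisibly.
#' @export
validate_embedding <- function(e) {
  if (!is.numeric(e) || length(e) != 2048L) {
    stop(sprintf("embedding must have length 2048, got %d", length(e)), call. = FALSE)
  }
  if (!all(is.finite(e))) stop("embedding contains non-finite values", call. = FALSE)
  invisible(e)
}

#' Run an embedding backend and validate its output
#' @param embedder function `(img, mask, ...) -> numeric(2048)`.
#' @param img [depth_image()].
#' @param mask [instance_mask()] or logical matrix.
#' @param ... passed to the embedder.
#' @return the validated embedding.
#' @export
embed_with <- function(embedder, img, mask, ...) {
  stopifnot(is.function(embedder))
  e <- embedder(img, mask, ...)
  validate_embedding(e)
  e
}

#' Fuse artificial and learned features
#'
#' Concatenates the 25 morphometric features (first) with the 2048 learned
#' values into a 2073-dimensional fused vector. No rescaling happens here;
#' normalisation, when wanted, is a separate training-time step.
#'
#' @param features named numeric vector of the 25 features
#'   ([extract_features()] output).
#' @param embedding numeric vector of length 2048.
#' @return a `fused_vector`: numeric vector of length 2073, named
#'   `f01_... f25_...`, `lf_0000 ... lf_2047`, with a per-position
#'   `provenance` attribute (`"artificial"` / `"learned"`).
#' @export
fuse <- function(features, embedding) {
  if (length(features) != 25L || !identical(names(features), feature_names())) {
    stop("`features` must be the named 25-feature vector", call. = FALSE)
  }
  validate_embedding(embedding)
  out <- c(unclass(features), as.numeric(embedding))
  names(out) <- c(feature_names(), sprintf("lf_%04d", 0:2047))
  structure(out,
            provenance = c(rep("artificial", 25L), rep("learned", 2048L)),
            class = "fused_vector")
}

#' Split a fused vector back into its blocks
#' @param fv a `fused_vector` from [fuse()].
#' @return list with `features` (named length 25) and `embedding`
#'   (length 2048).
#' @export
split_fused <- function(fv) {
  prov <- attr(fv, "provenance")
  if (is.null(prov) || length(fv) != 2073L) {
    stop("not a fused_vector", call. = FALSE)
  }
  v <- as.numeric(fv)
  names(v) <- names(fv)
  list(features = v[prov == "artificial"],
       embedding = unname(v[prov == "learned"]))
}

#' Fit min-max normalisation statistics on training rows
#'
#' Per-feature minimum and maximum computed on training data only.
#' Constant columns are flagged and passed through unchanged by
#' [normalize_apply()].
#'
#' @param x matrix or data frame of training rows.
#' @return list with `min`, `max` and logical `constant`, class
#'   `minmax_stats`.
#' @export
normalize_fit <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  structure(list(min = mins, max = maxs, constant = maxs == mins),
            class = "minmax_stats")
}

#' Apply min-max normalisation
#'
#' Scales each column to `[0, 1]` with the training statistics; values
#' outside the training range (possible on test rows) are clamped.
#' Constant columns pass through unchanged.
#'
#' @param x matrix, data frame or single row with the same columns as the
#'   training data.
#' @param stats a `minmax_stats` from [normalize_fit()].
#' @return scaled matrix.
#' @export
normalize_apply <- function(x, stats) {
  x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(stats$min)) {
    stop(sprintf("row length %d does not match the %d fitted features",
                 ncol(x), length(stats$min)), call. = FALSE)
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    if (stats$constant[j]) next
    out[, j] <- clamp((x[, j] - stats$min[j]) / (stats$max[j] - stats$min[j]), 0, 1)
  }
  out
}

#' Invert min-max normalisation (training-range values only)
#' @param x scaled matrix from [normalize_apply()].
#' @param stats the `minmax_stats` used to scale.
#' @return matrix on the original scale.
#' @export
normalize_invert <- function(x, stats) {
  x <- as.matrix(x)
  out <- x
  for (j in seq_len(ncol(x))) {
    if (stats$constant[j]) next
    out[, j] <- x[, j] * (stats$max[j] - stats$min[j]) + stats$min[j]
  }
  out
}
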