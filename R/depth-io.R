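# File I/O: 16-bit depth PNG (Z16 convention), 8-bit mask PNG, JET
# pseudo-colour rendering, and the feature-table CSV format.

png_chunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  crc_hex <- digest::digest(payload, algo = "crc32", serialize = FALSE)
  crc_hex <- paste0(strrep("0", 8L - nchar(crc_hex)), crc_hex)
  crc <- as.raw(strtoi(substring(crc_hex, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L))
  c(writeBin(length(data), raw(), size = 4, endian = "big"), payload, crc)
}

#' Write a depth image as 16-bit single-channel PNG
#'
#' Stores integer depth counts (mm by default) in a 16-bit grayscale PNG,
#' the Z16 convention of depth sensors; 0 encodes missing pixels. The
#' camera-to-ground distance is embedded as a `tEXt` chunk so the image
#' round-trips through [read_depth_z16()] losslessly, metadata included.
#' No installed package writes 16-bit PNG, so the (tiny) encoder lives
#' here; reading goes through libpng, which doubles as a check on the
#' writer.
#'
#' @param img [depth_image()] or numeric matrix of mm values.
#' @param path output file.
#' @param scale mm per stored count (default 1; use 0.1 for sensors that
#'   store tenths of a millimetre).
#' @return `path`, invisibly.
#' @export
write_depth_z16 <- function(img, path, scale = 1) {
  vals <- as_depth_values(img)
  counts <- round(vals / scale)
  if (any(counts < 0 | counts > 65535)) {
    stop("depth counts outside the 16-bit range [0, 65535]", call. = FALSE)
  }
  nr <- nrow(counts); nc <- ncol(counts)
  ihdr <- c(
    writeBin(nc, raw(), size = 4, endian = "big"),
    writeBin(nr, raw(), size = 4, endian = "big"),
    as.raw(c(16L, 0L, 0L, 0L, 0L))  # bit depth 16, grayscale, no interlace
  )
  m <- t(counts)                      # one column per scanline
  hi <- as.integer(m %/% 256)
  lo <- as.integer(m %% 256)
  scan <- matrix(0L, 1L + 2L * nc, nr)
  scan[seq(2L, 2L * nc, by = 2L), ] <- hi   # big-endian sample bytes
  scan[seq(3L, 2L * nc + 1L, by = 2L), ] <- lo
  idat <- memCompress(as.raw(scan), type = "gzip")  # zlib stream
  chunks <- list(png_chunk("IHDR", ihdr))
  if (is_depth_image(img)) {
    txt <- c(charToRaw("ground_distance"), as.raw(0L),
             charToRaw(format(img$ground_distance, digits = 15)))
    chunks <- c(chunks, list(png_chunk("tEXt", txt)))
    txt2 <- c(charToRaw("depth_scale_mm"), as.raw(0L),
              charToRaw(format(scale, digits = 15)))
    chunks <- c(chunks, list(png_chunk("tEXt", txt2)))
  }
  chunks <- c(chunks, list(png_chunk("IDAT", idat), png_chunk("IEND", raw(0))))
  sig <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))
  writeBin(c(sig, do.call(c, chunks)), path)
  invisible(path)
}

#' Read a 16-bit single-channel depth PNG
#'
#' Reads integer depth counts and converts them to mm. Files that are not
#' 16-bit or not single-channel are rejected with an error naming the
#' offending property. Pixels stored as 0 are missing.
#'
#' @param path PNG file.
#' @param ground_distance camera-to-ground distance in mm; if `NULL`, taken
#'   from the file's `ground_distance` text chunk when present (written by
#'   [write_depth_z16()]), otherwise estimated as the largest observed
#'   depth (valid for top-view scenes where ground pixels dominate).
#' @param scale mm per stored count; if `NULL`, taken from the file's
#'   metadata when present, else 1.
#' @return a [depth_image()].
#' @export
read_depth_z16 <- function(path, ground_distance = NULL, scale = NULL) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 16L) {
    stop(sprintf("expected a 16-bit PNG, got bit depth %d", info$bit.depth),
         call. = FALSE)
  }
  if (length(dim(arr)) != 2L) {
    stop(sprintf("expected a single-channel PNG, got %d channels",
                 dim(arr)[3]), call. = FALSE)
  }
  meta <- info$text
  if (is.null(scale)) {
    scale <- if (!is.null(meta) && "depth_scale_mm" %in% names(meta)) {
      as.numeric(meta[["depth_scale_mm"]])
    } else 1
  }
  vals <- matrix(round(arr * 65535) * scale, nrow(arr), ncol(arr))
  if (is.null(ground_distance)) {
    ground_distance <- if (!is.null(meta) && "ground_distance" %in% names(meta)) {
      as.numeric(meta[["ground_distance"]])
    } else if (any(vals > 0)) {
      max(vals)
    } else {
      stop("cannot infer ground_distance from an all-missing image; pass it explicitly",
           call. = FALSE)
    }
  }
  depth_image(vals, ground_distance = ground_distance, source = path)
}

#' Render a depth image through the JET colormap
#'
#' The classic piecewise-linear JET map: with
#' `t = clamp((d - dmin) / (dmax - dmin), 0, 1)`, the channels (0-255) are
#' `r = clamp(1.5 - |4t - 3|, 0, 1)`, `g = clamp(1.5 - |4t - 2|, 0, 1)`,
#' `b = clamp(1.5 - |4t - 1|, 0, 1)`, each scaled by 255 and rounded.
#' Missing pixels render black. This is the rendering used to turn depth
#' maps into pseudo-colour RGB images for visualisation and CNN input.
#'
#' @param img [depth_image()] or matrix (mm).
#' @param dmin,dmax depth range mapped onto the colormap; defaults to the
#'   range of non-missing values.
#' @return integer array `rows x cols x 3` with values 0-255.
#' @export
depth_to_jet <- function(img, dmin = NULL, dmax = NULL) {
  vals <- as_depth_values(img)
  present <- vals > 0
  if (is.null(dmin)) dmin <- min(vals[present])
  if (is.null(dmax)) dmax <- max(vals[present])
  if (!is.finite(dmin) || !is.finite(dmax) || dmin >= dmax) {
    stop("degenerate depth range: `dmin` must be smaller than `dmax`", call. = FALSE)
  }
  t <- clamp((vals - dmin) / (dmax - dmin), 0, 1)
  out <- array(0L, c(nrow(vals), ncol(vals), 3L))
  ch <- function(center) as.integer(round(255 * clamp(1.5 - abs(4 * t - center), 0, 1)))
  out[, , 1] <- ch(3) * present
  out[, , 2] <- ch(2) * present
  out[, , 3] <- ch(1) * present
  out
}

#' Write an RGB (JET) render as 8-bit PNG
#' @param rgb integer array from [depth_to_jet()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' Write an instance mask as 8-bit 0/255 PNG
#' @param mask [instance_mask()] or logical matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_mask_matrix(mask) * 1.0, path)
  invisible(path)
}

#' Read an 8-bit mask PNG
#' @param path PNG file (any pixel above half intensity is foreground).
#' @param instance_id id given to the mask.
#' @return an [instance_mask()].
#' @export
read_mask_png <- function(path, instance_id = 1L) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  instance_mask(arr > 0.5, instance_id = instance_id)
}

feature_table_known_extras <- c("instance_id", "animal_id", "weight_kg")

#' Write a feature table to CSV
#'
#' One row per instance; the 25 feature columns in their fixed order,
#' preceded by `instance_id`/`animal_id` and followed by `weight_kg` when
#' present. Plain UTF-8 CSV with `.` decimal separator.
#'
#' @param records data frame containing the 25 feature columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  missing_cols <- setdiff(feature_names(), names(records))
  if (length(missing_cols) > 0L) {
    stop("feature table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lead <- intersect(c("instance_id", "animal_id"), names(records))
  tail_cols <- intersect("weight_kg", names(records))
  out <- records[, c(lead, feature_names(), tail_cols), drop = FALSE]
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Columns are matched by name, so a permuted column order on disk is
#' accepted; missing feature columns are an error listing them. The result
#' uses the canonical column order.
#'
#' @param path CSV file written by [write_feature_table()] (or compatible).
#' @return data frame with the 25 feature columns (canonical order) plus
#'   any of `instance_id`, `animal_id`, `weight_kg` present in the file.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  missing_cols <- setdiff(feature_names(), names(df))
  if (length(missing_cols) > 0L) {
    stop("feature table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lead <- intersect(c("instance_id", "animal_id"), names(df))
  tail_cols <- intersect("weight_kg", names(df))
  df[, c(lead, feature_names(), tail_cols), drop = FALSE]
}
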