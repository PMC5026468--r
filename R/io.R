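#' Read ImageJ-style XY coordinate tables into point patterns
#'
#' Reads a CSV/TSV export with one row per cell body. The header must contain
#' `x` and `y` columns (case-insensitive; extra columns such as `Slice` are
#' ignored). Coordinates are multiplied by `scale` so the returned patterns
#' are in micrometres. If the file has an `image_id` column (or the metadata
#' table maps several images), one pattern per image is returned.
#'
#' @param path CSV or TSV file; the delimiter is sniffed from the header.
#' @param scale micrometres per pixel (`> 0`); use 1 for data already in um.
#' @param metadata optional data.frame with columns `image_id`, `retina_id`,
#'   `genotype` and optionally `window_x_min`, `window_y_min`,
#'   `window_x_max`, `window_y_max` (window in the same pixel units as the
#'   coordinates; scaled like them). Without a declared window the bounding
#'   box of the points is used, with a warning.
#' @return a list of `ppattern` objects, one per image id.
#' @export
read_points_table <- function(path, scale = 1, metadata = NULL) {
  stopifnot(scale > 0)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA)
  nm <- tolower(names(df))
  xi <- match("x", nm); yi <- match("y", nm)
  if (is.na(xi) || is.na(yi))
    stop("format error: header must contain x and y columns")
  xs <- suppressWarnings(as.numeric(df[[xi]]))
  ys <- suppressWarnings(as.numeric(df[[yi]]))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad) > 0)
    stop(sprintf("parse error: non-numeric coordinate in row %d", bad[1]))
  xs <- xs * scale
  ys <- ys * scale
  img_col <- match("image_id", nm)
  img <- if (!is.na(img_col)) as.character(df[[img_col]]) else
    rep("image1", length(xs))
  ids <- unique(img)
  if (length(ids) == 0)  # empty data section: still one (empty) pattern
    ids <- if (!is.null(metadata)) as.character(metadata$image_id) else
      "image1"
  lapply(ids, function(id) {
    sel <- img == id
    meta <- list(retina_id = NA_character_, genotype = NA_character_,
                 window = NULL)
    if (!is.null(metadata)) {
      row <- metadata[metadata$image_id == id, , drop = FALSE]
      if (nrow(row) == 1) {
        meta$retina_id <- as.character(row$retina_id)
        meta$genotype <- as.character(row$genotype)
        wc <- c("window_x_min", "window_y_min", "window_x_max", "window_y_max")
        if (all(wc %in% names(row)) && !anyNA(row[, wc]))
          meta$window <- as.numeric(row[, wc]) * scale
      }
    }
    point_pattern(xs[sel], ys[sel], window = meta$window, image_id = id,
                  retina_id = meta$retina_id, genotype = meta$genotype)
  })
}

#' Read a pairwise-comparison log
#'
#' CSV with columns `image_a`, `image_b`, `winner`, `rater`, one forced-choice
#' matchup per row in presentation order. Validates that every row compares
#' two distinct images and that the winner is one of them (no ties).
#'
#' @param path CSV file.
#' @return data.frame of validated records in file order.
#' @export
read_comparisons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_a", "image_b", "winner", "rater")
  if (!all(need %in% names(df)))
    stop("comparison log must have columns image_a, image_b, winner, rater")
  df <- df[, need]
  for (col in need) df[[col]] <- as.character(df[[col]])
  validate_comparisons(df)
  df
}

validate_comparisons <- function(df) {
  self_cmp <- which(df$image_a == df$image_b)
  if (length(self_cmp) > 0)
    stop(sprintf("validation error: self-comparison at row %d", self_cmp[1]))
  bad_win <- which(df$winner != df$image_a & df$winner != df$image_b)
  if (length(bad_win) > 0)
    stop(sprintf("validation error: winner not in matchup at row %d",
                 bad_win[1]))
  invisible(df)
}

#' Write (and read back) result tables and nested results
#'
#' Tables (data.frames, e.g. per-retina group tables) are written as CSV with
#' their column order preserved; nested results such as a DRP result are
#' written as JSON. `read_results()` inverts either, keyed on the file
#' extension, so a write/read round trip is lossless for tables.
#'
#' @param x a data.frame or a list-like result object.
#' @param path output file; `.csv` for tables, `.json` for nested results.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Two-dimensional intensity image with physical scale
#'
#' One- or two-channel grayscale image: a matrix, or an array
#' `[rows, cols, channels]` with 1 or 2 channels. Pixel (i, j) has its centre
#' at x = (j - 0.5) * scale, y = (i - 0.5) * scale micrometres (image
#' convention: origin at the top-left corner, y downward).
#'
#' @param pixels numeric matrix or 3-d array with last dimension 1 or 2;
#'   all intensities finite and non-negative.
#' @param scale micrometres per pixel, `> 0`.
#' @param channel_names character labels, one per channel.
#' @return an object of class `"intensity_image"`.
#' @export
intensity_image <- function(pixels, scale = 1,
                            channel_names = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1))
  if (length(dim(pixels)) != 3 || !(dim(pixels)[3] %in% c(1, 2)))
    stop("pixels must be a matrix or an array with 1 or 2 channels")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative")
  stopifnot(scale > 0)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(pixels)[3]))
  structure(list(pixels = pixels, scale = scale,
                 channel_names = channel_names),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Intensity image: %d x %d px, %d channel(s), %g um/px\n",
              d[1], d[2], d[3], x$scale))
  invisible(x)
}

#' Read a TIFF or PNG grayscale image
#'
#' Thin wrapper over the tiff/png packages producing an
#' [intensity_image()]. Multi-sample images with more than 2 channels are
#' rejected; use single- or two-channel grayscale exports.
#'
#' @param path `.tif`/`.tiff` or `.png` file.
#' @param scale micrometres per pixel.
#' @return an `intensity_image`.
#' @export
read_image <- function(path, scale = 1) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package")
      png::readPNG(path)
    },
    stop("unsupported image format: ", ext))
  intensity_image(px, scale = scale)
}
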