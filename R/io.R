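# Image and spot-list I/O.

#' Read a single-channel image (TIFF/PNG) as a matrix
#'
#' Delegated to [EBImage::readImage]; multi-frame files return the first
#' frame, and `scale` (default 65535, the 16-bit range) converts EBImage's
#' [0, 1] normalization back to integer counts.
#'
#' @param path Path to the image file.
#' @param scale Multiplier applied to the normalized pixel values.
#' @return A numeric matrix in the package's `[x, y]` convention.
#' @export
read_image <- function(path, scale = 65535) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) > 2L) d <- d[, , 1]
  d * scale
}

#' Write a matrix as a 16-bit TIFF
#'
#' Label masks and shell maps are written as integer-valued 16-bit
#' grayscale TIFFs via [EBImage::writeImage].
#'
#' @param x Numeric/integer matrix.
#' @param path Output path (`.tif`/`.tiff`).
#' @param scale Divisor normalizing values into EBImage's [0, 1] range.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, scale = 65535) {
  EBImage::writeImage(EBImage::Image(x / scale), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read or write a spot list as TSV
#'
#' Tab-separated with a header; the columns are those of a `"spot_set"`
#' (`x`, `y`, `sigma`, `amplitude`, ...). Lines starting with `#` are
#' skipped on read.
#'
#' @param path File path.
#' @return `read_spots`: a `"spot_set"` data frame.
#' @export
read_spots <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("spot list must have x and y columns")
  structure(df, class = c("spot_set", "data.frame"))
}

#' @rdname read_spots
#' @param spots A `"spot_set"` or compatible data frame.
#' @export
write_spots <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
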