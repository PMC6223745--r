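#' Read a plate image as a grayscale matrix
#'
#' Reads 8- or 16-bit PNG (and TIFF when the tiff package is available)
#' into a numeric matrix in `[0, 1]`, rows = image rows (y), columns = x.
#' Multi-channel images are averaged to grayscale.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a binary or grayscale matrix as an 8-bit PNG
#'
#' Foreground convention: background 0, foreground 255 (a 0/1 matrix is
#' scaled to the full 8-bit range).
#'
#' @param img Numeric/integer/logical matrix; values in `[0, 1]` or `[0, 255]`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  m <- img * 1
  if (max(m) > 1) m <- m / 255
  png::writePNG(m, path)
  invisible(path)
}
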