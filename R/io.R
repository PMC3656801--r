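# Reading and writing of the standard raster formats. Images are 8-bit; the
# png/tiff readers return [0,1] doubles, rescaled here to the 0..255 span
# used throughout the package.

#' Read an 8-bit RGB image
#'
#' Reads a PNG or TIFF file (format by extension) and returns an
#' H x W x 3 array of values in `[0, 255]`. Greyscale files are replicated
#' to three channels; an alpha channel is dropped.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return H x W x 3 numeric array.
#' @export
readRGBImage <- function(path) {
  a <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
         tiff::readTIFF(path)
       else stop("unsupported image format: ", path)
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  if (dim(a)[3] == 1L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Write an RGB array
#'
#' @param rgb H x W x 3 array of 8-bit values.
#' @param path output path; `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
writeRGBImage <- function(rgb, path) {
  a <- asRGBArray(rgb) / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(a, path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(a, path, compression = "none")
  else stop("unsupported image format: ", path)
  invisible(path)
}

#' Write an intensity image as 8-bit greyscale PNG
#'
#' @param img an [IntensityImage] or numeric matrix in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGreyPNG <- function(img, path) {
  m <- asIntensityMatrix(img)
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Write a binary mask as PNG
#'
#' Objects (0) are written black, background (1) white.
#'
#' @param mask a [BinaryMask] or `{0,1}` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  m <- asMaskMatrix(mask)
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask from an image file
#'
#' Pixels darker than mid-grey become objects (0).
#'
#' @param path PNG or TIFF path.
#' @return a [BinaryMask].
#' @export
readMask <- function(path) {
  a <- readRGBImage(path)
  new("BinaryMask", pixels = (a[, , 1] >= 128) + 0)
}
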